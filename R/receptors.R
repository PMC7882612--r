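#' A1 visual-pigment nomogram sensitivity template
#'
#' Evaluates the alpha-band of the Govardovskii A1 rhodopsin template at a
#' given peak wavelength and max-normalizes it to 1. The template is
#' unimodal in the pigment's absorbing range, which is what the opponency
#' model requires of a receptor sensitivity; the small beta (UV shoulder)
#' band is deliberately omitted so each template represents a single
#' spectral class.
#'
#' @param lambda_max Peak wavelength (nm), in 300--650.
#' @param grid A [wl_grid()].
#' @return A sensitivity [spectrum()] with maximum 1 at `lambda_max` (to
#'   grid resolution).
#' @references Govardovskii-type template: S(x) =
#'   1 / (exp(A (a - x)) + exp(B (b - x)) + exp(C (c - x)) + D) with
#'   x = lambda_max / lambda.
#' @export
nomogram_sensitivity <- function(lambda_max, grid) {
  stopifnot(inherits(grid, "wl_grid"))
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      lambda_max < 300 || lambda_max > 650) {
    stop("nomogram_sensitivity: lambda_max must be a single value in [300, 650] nm")
  }
  wl <- wl_seq(grid)
  v <- .a1_template(lambda_max, wl)
  spectrum(grid, v / max(v), kind = "sensitivity",
           label = sprintf("A1_%gnm", lambda_max))
}

# alpha-band A1 template (Govardovskii et al. parameterization),
# unnormalized. The raw template's maximum sits a fraction of a nanometre
# away from lambda_max; the inverse-wavelength axis is rescaled by the
# template's own argmax so the curve peaks at lambda_max exactly.
.a1_template <- function(lambda_max, wl) {
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; c <- 1.104
  f <- function(x) 1 / (exp(A * (a - x)) + exp(B * (b - x)) +
                          exp(C * (c - x)) + D)
  xs <- stats::optimize(f, c(0.8, 1.2), maximum = TRUE, tol = 1e-10)$maximum
  f(xs * lambda_max / wl)
}

#' Receptor set for the fly opponency model
#'
#' Bundles the four photoreceptor sensitivities the categorical fly
#' colour-opponency model uses: the pale and yellow ommatidial R7/R8 pairs
#' (R7p, R7y, R8p, R8y). Sensitivities may come from tabulated CSV curves
#' (via [read_spectra_csv()] + [resample()]) or, by default, from nomogram
#' templates at stand-in peak wavelengths. Peak wavelengths of the fly
#' receptors used in the original measurements are not published, so the
#' defaults (R7p 330, R7y 350, R8p 460, R8y 530 nm) are explicit stand-ins
#' and should be overridden when measured curves are available.
#'
#' @param grid A [wl_grid()].
#' @param lambda_max Named numeric vector with entries `R7p`, `R7y`, `R8p`,
#'   `R8y` (nm), used when `sensitivities` is `NULL`.
#' @param sensitivities Optional named list of four sensitivity
#'   [spectrum()] objects on `grid` (keys as above); each is max-normalized.
#' @return An object of class `receptor_set`: a named list of four
#'   sensitivity spectra.
#' @export
receptor_set <- function(grid,
                         lambda_max = c(R7p = 330, R7y = 350,
                                        R8p = 460, R8y = 530),
                         sensitivities = NULL) {
  keys <- c("R7p", "R7y", "R8p", "R8y")
  if (is.null(sensitivities)) {
    stopifnot(all(keys %in% names(lambda_max)))
    sensitivities <- lapply(keys, function(k) {
      s <- nomogram_sensitivity(lambda_max[[k]], grid)
      s$label <- k
      s
    })
    names(sensitivities) <- keys
  } else {
    if (!all(keys %in% names(sensitivities))) {
      stop("receptor_set: sensitivities must be named R7p, R7y, R8p, R8y")
    }
    sensitivities <- lapply(sensitivities[keys], function(s) {
      stopifnot(inherits(s, "spectrum"), s$kind == "sensitivity")
      if (!isTRUE(all.equal(s$wl, wl_seq(grid)))) {
        stop("receptor_set: sensitivity not on the requested grid")
      }
      s$values <- s$values / max(s$values)
      s
    })
  }
  structure(sensitivities, class = "receptor_set")
}

#' @export
print.receptor_set <- function(x, ...) {
  peaks <- vapply(x, function(s) s$wl[which.max(s$values)], numeric(1))
  cat("<receptor_set> peaks (nm):",
      paste(sprintf("%s=%g", names(peaks), peaks), collapse = ", "), "\n")
  invisible(x)
}
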