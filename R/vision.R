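#' Photoreceptor quantum catches
#'
#' Integrates reflectance x illuminant x sensitivity over wavelength
#' (trapezoidal rule on the common grid) for each of the four fly
#' receptors. This is the photon signal each receptor class receives from
#' a stimulus viewed under the given illuminant.
#'
#' @param reflectance A reflectance [spectrum()].
#' @param illuminant An illuminant [spectrum()] on the same grid.
#' @param receptors A [receptor_set()] on the same grid.
#' @return Named numeric vector of class `quantum_catches` with entries
#'   `R7p`, `R7y`, `R8p`, `R8y` (relative units, >= 0).
#' @export
quantum_catch <- function(reflectance, illuminant, receptors) {
  stopifnot(inherits(reflectance, "spectrum"), inherits(illuminant, "spectrum"),
            inherits(receptors, "receptor_set"))
  wl <- reflectance$wl
  if (!isTRUE(all.equal(wl, illuminant$wl))) {
    stop("quantum_catch: grid error, reflectance and illuminant on different grids")
  }
  q <- vapply(receptors, function(s) {
    if (!isTRUE(all.equal(wl, s$wl))) {
      stop("quantum_catch: grid error, receptor sensitivity on a different grid")
    }
    f <- reflectance$values * illuminant$values * s$values
    .trapz(wl, f)
  }, numeric(1))
  structure(q, class = "quantum_catches")
}

.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Quadrant label in the fly opponency plane
#'
#' The opponency plane's four quadrants are the model's distinguishable
#' colour categories. Coordinates within `tol` of an axis are labelled
#' `"boundary"` rather than assigned to a quadrant, so threshold verdicts
#' cannot flip on numerical noise.
#'
#' @param x,y Opponency coordinates.
#' @param tol Axis tolerance (default `1e-12`).
#' @return One of `"p+y+"`, `"p+y-"`, `"p-y+"`, `"p-y-"`, `"boundary"`.
#' @export
classify_quadrant <- function(x, y, tol = 1e-12) {
  stopifnot(is.finite(x), is.finite(y))
  if (abs(x) <= tol || abs(y) <= tol) return("boundary")
  paste0("p", if (x > 0) "+" else "-", "y", if (y > 0) "+" else "-")
}

#' Map a stimulus into the categorical fly opponency plane
#'
#' Applies von Kries adaptation (each stimulus catch divided by the
#' corresponding background catch), transforms relative catches q to
#' receptor excitations, and takes the two opponent differences:
#' `x = e(R7p) - e(R8p)`, `y = e(R7y) - e(R8y)`. With the default
#' hyperbolic excitation `e = q / (q + 1)` the adapting background maps to
#' the origin exactly, so distance from the origin measures chromatic
#' contrast against the background, and both coordinates are bounded in
#' (-1, 1).
#'
#' @param stimulus A `quantum_catches` vector for the stimulus.
#' @param background A `quantum_catches` vector for the adapting
#'   background; all four catches must be positive.
#' @param transform `"hyperbolic"` (default) for `e = q/(q+1)`, or
#'   `"linear"` for `e = q` (sensitivity analysis; the background then maps
#'   to the origin via the offset `e - 1`).
#' @return An object of class `vision_point`: list with `x`, `y`,
#'   `quadrant`, `dist_origin`.
#' @export
troje_point <- function(stimulus, background,
                        transform = c("hyperbolic", "linear")) {
  transform <- match.arg(transform)
  stimulus <- unclass(stimulus); background <- unclass(background)
  keys <- c("R7p", "R7y", "R8p", "R8y")
  stopifnot(all(keys %in% names(stimulus)), all(keys %in% names(background)))
  if (any(!is.finite(background[keys])) || any(background[keys] <= 0)) {
    stop("troje_point: adaptation error, background catches must all be > 0")
  }
  q <- stimulus[keys] / background[keys]
  e <- switch(transform,
              hyperbolic = q / (q + 1),
              linear = q)
  ref <- switch(transform, hyperbolic = 0.5, linear = 1)
  x <- (e[["R7p"]] - ref) - (e[["R8p"]] - ref)
  y <- (e[["R7y"]] - ref) - (e[["R8y"]] - ref)
  vision_point(x, y)
}

#' @rdname troje_point
#' @param x,y Opponency coordinates.
#' @export
vision_point <- function(x, y) {
  structure(list(x = x, y = y,
                 quadrant = classify_quadrant(x, y),
                 dist_origin = sqrt(x^2 + y^2)),
            class = "vision_point")
}

#' @export
print.vision_point <- function(x, ...) {
  cat(sprintf("<vision_point> (%.4f, %.4f) %s, dist %.4f\n",
              x$x, x$y, x$quadrant, x$dist_origin))
  invisible(x)
}

#' Image-level opponency point from multiple measured regions
#'
#' Quantum catches are computed for each measured region of a stimulus
#' (e.g., five patches on the ray florets of one image), averaged per
#' receptor, and the averaged catches are mapped against the background
#' catch of the same image. Catch averaging happens before the excitation
#' transform.
#'
#' @param region_spectra Non-empty list of reflectance spectra.
#' @param background Background reflectance [spectrum()].
#' @param illuminant,receptors As in [quantum_catch()].
#' @param transform Passed to [troje_point()].
#' @return A `vision_point`.
#' @export
region_mean_point <- function(region_spectra, background, illuminant,
                              receptors, transform = "hyperbolic") {
  if (length(region_spectra) < 1) {
    stop("region_mean_point: input error, need >= 1 region spectrum")
  }
  qs <- vapply(region_spectra,
               function(s) unclass(quantum_catch(s, illuminant, receptors)),
               numeric(4))
  qbar <- structure(rowMeans(qs), class = "quantum_catches")
  qbg <- quantum_catch(background, illuminant, receptors)
  troje_point(qbar, qbg, transform = transform)
}

#' Species cloud in the opponency plane
#'
#' A set of image-level points for one species (replicates across images),
#' with their centroid.
#'
#' @param label Species label.
#' @param points Non-empty list of `vision_point`s.
#' @return Object of class `species_cloud` with `label`, `points`,
#'   `centroid` (named vector `x`, `y`).
#' @export
species_cloud <- function(label, points) {
  if (length(points) < 1) stop("species_cloud: input error, need >= 1 point")
  stopifnot(all(vapply(points, inherits, logical(1), "vision_point")))
  xs <- vapply(points, `[[`, numeric(1), "x")
  ys <- vapply(points, `[[`, numeric(1), "y")
  structure(list(label = label, points = points,
                 centroid = c(x = mean(xs), y = mean(ys))),
            class = "species_cloud")
}

#' Euclidean distance between two species centroids
#'
#' The model's discriminability measure: how far apart two stimulus clouds
#' sit in the opponency plane.
#'
#' @param a,b `species_cloud` objects.
#' @return Nonnegative distance (opponency units).
#' @export
centroid_distance <- function(a, b) {
  stopifnot(inherits(a, "species_cloud"), inherits(b, "species_cloud"))
  sqrt(sum((a$centroid - b$centroid)^2))
}

#' Minimum-discrimination threshold map
#'
#' Experimentally determined minimum colour-discrimination distances are
#' only available for two quadrants of the opponency plane (0.021 in p-y-,
#' 0.059 in p+y- for syrphid flies); verdicts in other quadrants are
#' `"unknown"` unless a threshold is supplied.
#'
#' @param ... Named thresholds, names among the quadrant labels.
#' @return Named numeric vector of class `threshold_map`.
#' @export
threshold_map <- function(...) {
  th <- c(...)
  if (length(th) == 0) th <- c("p-y-" = 0.021, "p+y-" = 0.059)
  stopifnot(is.numeric(th), all(th > 0),
            all(names(th) %in% c("p+y+", "p+y-", "p-y+", "p-y-")))
  structure(th, class = "threshold_map")
}

#' Detectability verdict for an opponency point
#'
#' A stimulus is called detectable when its distance from the origin (the
#' adapted background) reaches the minimum-discrimination threshold of the
#' quadrant it falls in; `"unknown"` when its quadrant has no threshold
#' (including boundary points).
#'
#' @param point A `vision_point`.
#' @param thresholds A [threshold_map()].
#' @return `"detectable"`, `"not_detectable"`, or `"unknown"`.
#' @export
detectability_verdict <- function(point, thresholds = threshold_map()) {
  stopifnot(inherits(point, "vision_point"), inherits(thresholds, "threshold_map"))
  q <- point$quadrant
  if (!q %in% names(thresholds)) return("unknown")
  if (point$dist_origin >= thresholds[[q]]) "detectable" else "not_detectable"
}

#' Welch's two-sample t-test on detectability distances
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' used to compare a species' distances from the origin across soil
#' backgrounds. When both samples are constant and equal, the test
#' degenerates to `t = 0, p = 1` with pooled df.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param one_sided If `TRUE`, the p-value is for the alternative
#'   `mean(a) > mean(b)`; default two-sided.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b, one_sided = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("welch_t: sample-size error, each sample needs n >= 2")
  }
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = na + nb - 2, p = 1))
    }
    stop("welch_t: both samples constant with different means")
  }
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- if (one_sided) stats::pt(t, df, lower.tail = FALSE)
       else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
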