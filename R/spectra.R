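#' Wavelength grid
#'
#' A regular wavelength grid on which all spectra entering the vision model
#' are co-registered. The grid runs `start, start + step, ..., stop` exactly,
#' so `(stop - start)` must be an integer multiple of `step`.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Increment (nm); must be positive.
#'
#' @return An object of class `wl_grid` with fields `start_nm`, `stop_nm`,
#'   `step_nm`.
#'
#' @details The default grid used throughout the package is 300--700 nm at
#'   1 nm, spanning both the UV band (where the orange daisies carry a
#'   secondary reflectance peak) and the visible band.
#'
#' @examples
#' g <- wl_grid(300, 700, 1)
#' length(wl_seq(g))
#' @export
wl_grid <- function(start_nm = 300, stop_nm = 700, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("wl_grid: step_nm must be > 0")
  if (start_nm >= stop_nm) stop("wl_grid: start_nm must be < stop_nm")
  k <- (stop_nm - start_nm) / step_nm
  if (abs(k - round(k)) > 1e-8) {
    stop("wl_grid: (stop_nm - start_nm) must be an integer multiple of step_nm")
  }
  structure(list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm),
            class = "wl_grid")
}

#' @rdname wl_grid
#' @param grid A `wl_grid`.
#' @export
wl_seq <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  seq(grid$start_nm, grid$stop_nm, by = grid$step_nm)
}

#' Spectrum container
#'
#' A wavelength-indexed vector of nonnegative values: a reflectance, an
#' illuminant (relative photon flux or power), or a receptor sensitivity.
#'
#' @param grid A [wl_grid()].
#' @param values Numeric vector, one value per grid point, all `>= 0`.
#'   Reflectances are additionally required to stay below 1.5 (calibration
#'   overshoot above 1 is tolerated; larger values indicate gross errors).
#' @param kind One of `"reflectance"`, `"illuminant"`, `"sensitivity"`.
#' @param label Optional name carried through tables and plots.
#'
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(grid, values, kind = c("reflectance", "illuminant",
                                            "sensitivity"), label = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "wl_grid"))
  wl <- wl_seq(grid)
  values <- as.numeric(values)
  if (length(values) != length(wl)) {
    stop(sprintf("spectrum: expected %d values for this grid, got %d",
                 length(wl), length(values)))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("spectrum: values must be finite")
  }
  if (any(values < 0)) stop("spectrum: values must be >= 0")
  if (kind == "reflectance" && any(values > 1.5)) {
    stop("spectrum: reflectance values above 1.5 indicate a calibration error")
  }
  structure(list(grid = grid, wl = wl, values = values, kind = kind,
                 label = label),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s%s: %g-%g nm (step %g), range [%.4g, %.4g]\n",
              x$kind,
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$grid$start_nm, x$grid$stop_nm, x$grid$step_nm,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Read labelled spectra from CSV
#'
#' Reads the package's spectra dialect: first column `wavelength_nm`
#' (strictly increasing), one spectrum per subsequent column, `#` comments.
#' Negative values (spectrometer noise) are clipped to 0 with a warning.
#'
#' @param path Path to a CSV file.
#' @param kind Spectrum kind applied to every column (see [spectrum()]).
#' @return A named list of irregular spectra, each a list with fields `wl`,
#'   `values`, `kind`, `label` (class `raw_spectrum`); pass through
#'   [resample()] to place them on a [wl_grid()].
#' @export
read_spectra_csv <- function(path, kind = c("reflectance", "illuminant",
                                            "sensitivity")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("read_spectra_csv: no such file '%s'", path))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("read_spectra_csv: need a wavelength column plus >= 1 value column")
  if (nrow(df) < 2) stop("read_spectra_csv: format error, need >= 2 wavelength rows")
  num <- lapply(seq_len(ncol(df)), function(j) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & nzchar(trimws(df[[j]])))
    if (length(bad) || anyNA(v)) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stop(sprintf("read_spectra_csv: non-numeric cell at row %d, column '%s'",
                   row, names(df)[j]))
    }
    v
  })
  wl <- num[[1]]
  if (any(diff(wl) <= 0)) {
    stop("read_spectra_csv: format error, wavelengths must be strictly increasing")
  }
  out <- lapply(seq_along(num)[-1], function(j) {
    v <- num[[j]]
    if (any(v < 0)) {
      warning(sprintf("read_spectra_csv: clipped %d negative value(s) to 0 in column '%s'",
                      sum(v < 0), names(df)[j]))
      v[v < 0] <- 0
    }
    structure(list(wl = wl, values = v, kind = kind, label = names(df)[j]),
              class = "raw_spectrum")
  })
  names(out) <- names(df)[-1]
  out
}

#' Write labelled spectra to CSV
#'
#' Inverse of [read_spectra_csv()]: all spectra must share one grid.
#'
#' @param spectra A list of [spectrum()] objects on a common grid.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1)
  wl <- spectra[[1]]$wl
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wl, wl))) stop("write_spectra_csv: spectra on different grids")
  }
  labs <- vapply(seq_along(spectra), function(i) {
    if (!is.null(spectra[[i]]$label)) spectra[[i]]$label
    else if (!is.null(names(spectra)[i]) && nzchar(names(spectra)[i])) names(spectra)[i]
    else paste0("spectrum_", i)
  }, character(1))
  # full-precision output so write -> read round-trips values exactly
  df <- data.frame(wavelength_nm = sprintf("%.17g", wl), check.names = FALSE)
  for (i in seq_along(spectra)) {
    df[[labs[i]]] <- sprintf("%.17g", spectra[[i]]$values)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation onto the target grid. The spectrum's native range
#' must cover the grid; gaps at either end of at most `edge_tol_nm` are
#' filled with the terminal value, larger gaps are an error (no silent
#' extrapolation).
#'
#' @param x A [spectrum()] or the `raw_spectrum` returned by
#'   [read_spectra_csv()].
#' @param grid Target [wl_grid()].
#' @param edge_tol_nm Maximum permitted edge extrapolation (nm); default 5.
#' @return A [spectrum()] on `grid`.
#' @export
resample <- function(x, grid, edge_tol_nm = 5) {
  stopifnot(inherits(grid, "wl_grid"))
  if (!inherits(x, c("spectrum", "raw_spectrum"))) {
    stop("resample: x must be a spectrum")
  }
  target <- wl_seq(grid)
  lo <- min(x$wl); hi <- max(x$wl)
  if (min(target) < lo - edge_tol_nm || max(target) > hi + edge_tol_nm) {
    miss <- character(0)
    if (min(target) < lo - edge_tol_nm) {
      miss <- c(miss, sprintf("%g-%g nm", min(target), lo))
    }
    if (max(target) > hi + edge_tol_nm) {
      miss <- c(miss, sprintf("%g-%g nm", hi, max(target)))
    }
    stop(sprintf("resample: coverage error, spectrum does not cover %s",
                 paste(miss, collapse = " and ")))
  }
  v <- stats::approx(x$wl, x$values, xout = target, rule = 2)$y
  v[v < 0] <- 0   # guards against tiny negative round-off
  spectrum(grid, v, kind = x$kind, label = x$label)
}
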