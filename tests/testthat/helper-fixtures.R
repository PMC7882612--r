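# Shared fixtures: small grids, analytic spectra, and independent oracles.

default_grid <- function() wl_grid(300, 700, 1)

# analytic Gaussian reflectance evaluated on any wavelength vector
gaussian_refl_fun <- function(peak, sd, amp = 0.8) {
  function(wl) amp * exp(-0.5 * ((wl - peak) / sd)^2)
}

# smooth analytic illuminant (broad raised profile), used where the oracle
# needs the integrand at arbitrary wavelengths
smooth_illum_fun <- function() {
  function(wl) 0.3 + 0.7 * exp(-0.5 * ((wl - 520) / 160)^2)
}

spectrum_from_fun <- function(f, grid, kind) {
  spectrum(grid, f(wl_seq(grid)), kind = kind)
}

# independent trapezoidal integration at an arbitrary (fine) step
trapz_oracle <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# brute-force quantum catch from analytic functions on a fine grid
fine_grid_catch <- function(refl_fun, illum_fun, lambda_max,
                            lo = 300, hi = 700, step = 0.1) {
  wl <- seq(lo, hi, by = step)
  s <- daisyfly:::.a1_template(lambda_max, wl)
  s <- s / max(daisyfly:::.a1_template(lambda_max, seq(lo, hi, by = 1)))
  trapz_oracle(wl, refl_fun(wl) * illum_fun(wl) * s)
}

# write a temporary spectra CSV and return its path
write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
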