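# CIE standard illuminant D65, relative spectral power distribution at
# 10 nm from 300 to 780 nm (normalized to 100 at 560 nm).
.d65_table <- data.frame(
  wl = seq(300, 780, by = 10),
  power = c(
    0.0341, 3.2945, 11.7652, 20.2360, 28.6447, 37.0535, 46.6383, 52.0891,
    49.9755, 54.6482, 82.7549, 91.4860, 93.4318, 86.6823, 104.8650,
    117.0080, 117.8120, 114.8610, 115.9230, 108.8110, 109.3540, 107.8020,
    104.7900, 107.6890, 104.4050, 104.0460, 100.0000, 96.3342, 95.7880,
    88.6856, 90.0062, 89.5991, 87.6987, 83.2886, 83.6992, 80.0268,
    80.2146, 82.2778, 78.2842, 69.7213, 71.6091, 74.3490, 61.6040,
    69.8856, 75.0870, 63.5927, 46.4182, 66.8054, 63.3828
  )
)

#' Standard daylight illuminant D65
#'
#' Returns the CIE D65 relative spectral power distribution resampled to a
#' grid, by default converted from energy to photon units (power multiplied
#' by wavelength, since photoreceptors count photons rather than energy)
#' and renormalized to a maximum of 1. The bundled table is tabulated at
#' 10 nm over 300--780 nm and interpolated linearly.
#'
#' @param grid A [wl_grid()] within 300--780 nm.
#' @param photon_units If `TRUE` (default), convert relative power to
#'   relative photon flux before normalizing. The von Kries adaptation in
#'   [troje_point()] makes downstream coordinates invariant to the overall
#'   illuminant scale, but not to this spectral reweighting.
#' @return An illuminant [spectrum()] with maximum value 1.
#' @seealso [equal_energy_illuminant()] for a flat substitute.
#' @export
d65_illuminant <- function(grid, photon_units = TRUE) {
  stopifnot(inherits(grid, "wl_grid"))
  if (grid$start_nm < min(.d65_table$wl) || grid$stop_nm > max(.d65_table$wl)) {
    stop(sprintf("d65_illuminant: coverage error, grid must lie within %g-%g nm",
                 min(.d65_table$wl), max(.d65_table$wl)))
  }
  wl <- wl_seq(grid)
  p <- stats::approx(.d65_table$wl, .d65_table$power, xout = wl)$y
  if (photon_units) p <- p * wl
  spectrum(grid, p / max(p), kind = "illuminant", label = "D65")
}

#' Equal-energy (flat) illuminant
#'
#' A constant-valued illuminant, useful as a neutral substitute when no
#' daylight assumption is wanted.
#'
#' @param grid A [wl_grid()].
#' @return An illuminant [spectrum()] with all values 1.
#' @export
equal_energy_illuminant <- function(grid) {
  spectrum(grid, rep(1, length(wl_seq(grid))), kind = "illuminant",
           label = "equal_energy")
}
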