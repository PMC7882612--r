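# Named spectral components per stimulus class. Shapes follow the
# qualitative description of the measured curves: white daisies reflect
# strongly and flatly across 400-700 nm but absorb in the UV; orange
# daisies are dark below ~550 nm, bright above, and carry a secondary UV
# peak near 330-370 nm; pale granite soil is moderately and fairly flatly
# reflective; red marine sand is dark at short wavelengths and rises
# toward the red.
.spectrum_defaults <- list(
  white_flower = list(base_amp = 0.85, base_mid = 410, base_width = 12,
                      uv_amp = 0.00, uv_center = 350, uv_width = 20,
                      floor = 0.04),
  orange_flower = list(base_amp = 0.80, base_mid = 565, base_width = 15,
                       uv_amp = 0.22, uv_center = 350, uv_width = 18,
                       floor = 0.05),
  pale_soil = list(base_amp = 0.25, base_mid = 420, base_width = 60,
                   uv_amp = 0.00, uv_center = 350, uv_width = 20,
                   floor = 0.18),
  red_soil = list(base_amp = 0.30, base_mid = 585, base_width = 30,
                  uv_amp = 0.00, uv_center = 350, uv_width = 20,
                  floor = 0.06)
)

#' Generate a synthetic reflectance spectrum
#'
#' Builds a reflectance curve as a sigmoidal base (long-pass edge) plus an
#' optional UV Gaussian component plus truncated Gaussian noise, clipped
#' to [0, 1]. The four named kinds emulate the study system's stimuli
#' (see the package vignette); individual components can be overridden to
#' emulate, e.g., the UV-peak position/intensity contrast between the two
#' orange species.
#'
#' @param kind One of `"white_flower"`, `"orange_flower"`, `"pale_soil"`,
#'   `"red_soil"`.
#' @param grid A [wl_grid()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(parameters, seed)`.
#' @param noise_sd Standard deviation of pointwise reflectance noise
#'   (default 0.01).
#' @param overrides Named list replacing any of the component parameters
#'   (`base_amp`, `base_mid`, `base_width`, `uv_amp`, `uv_center`,
#'   `uv_width`, `floor`).
#' @param label Optional label (defaults to `kind`).
#' @return A reflectance [spectrum()].
#' @export
gen_spectrum <- function(kind = c("white_flower", "orange_flower",
                                  "pale_soil", "red_soil"),
                         grid = wl_grid(), seed = 1, noise_sd = 0.01,
                         overrides = list(), label = NULL) {
  kind <- match.arg(kind)
  p <- utils::modifyList(.spectrum_defaults[[kind]], overrides)
  stopifnot(p$base_amp >= 0, p$uv_amp >= 0, noise_sd >= 0)
  wl <- wl_seq(grid)
  stopifnot(p$base_mid >= min(wl), p$base_mid <= max(wl))
  v <- p$floor +
    p$base_amp / (1 + exp(-(wl - p$base_mid) / p$base_width)) +
    p$uv_amp * exp(-0.5 * ((wl - p$uv_center) / p$uv_width)^2)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    noise <- stats::rnorm(length(wl), 0, noise_sd)
    noise <- pmin(pmax(noise, -3 * noise_sd), 3 * noise_sd)
    v <- v + noise
  }
  v <- pmin(pmax(v, 0), 1)
  spectrum(grid, v, kind = "reflectance",
           label = if (is.null(label)) kind else label)
}

#' Generate a synthetic landscape survey
#'
#' Simulates a set of survey sites with fly densities and a binary site
#' flower colour driven by a known logistic link, in the format the
#' mosaic analysis consumes. Densities of the orange-community fly
#' (`M_capensis`) follow a zero-inflated log-normal; the white-community
#' fly (`C_nigripes`) is present mainly where the first is absent.
#' Site colour is Bernoulli with
#' `P(orange) = plogis(beta0 + beta1 * density(M_capensis))`; in
#' `separation_mode` colour is instead fully determined by `C_nigripes`
#' presence (orange only where it is absent), reproducing complete
#' separation for the ordinary logistic fit. Each site density is then
#' factored into per-plant-species records (flies per flowerhead times
#' flowerheads per m^2) whose site sum reconstructs the drawn density
#' exactly.
#'
#' @param n_sites Number of sites (default 54).
#' @param beta0,beta1 Logistic intercept and slope linking `M_capensis`
#'   density (individuals per m^2) to the probability of an orange site.
#'   Defaults (-2, 3) give a strong but estimable association across the
#'   realized density range (up to roughly 1.7 per m^2).
#' @param zero_prob Probability a fly species is absent from a site
#'   (default 0.3).
#' @param meanlog,sdlog Log-normal density parameters for `M_capensis`
#'   (defaults chosen so maxima near 1.7 per m^2 occur); `C_nigripes`
#'   densities are scaled by `cn_scale` (default 2.2, maxima near 3.7).
#' @param cn_scale Multiplier for `C_nigripes` densities.
#' @param separation_mode Logical, see above.
#' @param seed Integer seed.
#' @return List with `records` (survey rows: `site_id`, `fly_species`,
#'   `plant_species`, `flies_per_flowerhead`, `flowerheads_per_m2`),
#'   `sites` (per-site `site_id`, `density_mc`, `density_cn`,
#'   `color_code`), and the generating parameters.
#' @export
gen_landscape <- function(n_sites = 54, beta0 = -2, beta1 = 3,
                          zero_prob = 0.3, meanlog = log(0.35), sdlog = 0.8,
                          cn_scale = 2.2, separation_mode = FALSE, seed = 1) {
  stopifnot(n_sites >= 2)
  set.seed(as.integer(seed))
  d_mc <- ifelse(stats::runif(n_sites) < zero_prob, 0,
                 stats::rlnorm(n_sites, meanlog, sdlog))
  # white-community fly: high where the orange-community fly is absent
  d_cn <- ifelse(d_mc > 0 & stats::runif(n_sites) < 0.85, 0,
                 cn_scale * stats::rlnorm(n_sites, meanlog, sdlog))
  if (separation_mode) {
    color <- as.numeric(d_cn == 0)
  } else {
    color <- stats::rbinom(n_sites, 1, stats::plogis(beta0 + beta1 * d_mc))
  }
  site_ids <- sprintf("S%03d", seq_len(n_sites))
  recs <- list()
  for (i in seq_len(n_sites)) {
    for (fly in c("M_capensis", "C_nigripes")) {
      dens <- if (fly == "M_capensis") d_mc[i] else d_cn[i]
      n_plants <- sample(1:4, 1)
      share <- stats::runif(n_plants)
      share <- share / sum(share)
      heads <- stats::runif(n_plants, 2, 40)
      recs[[length(recs) + 1]] <- data.frame(
        site_id = site_ids[i],
        fly_species = fly,
        plant_species = sprintf("plant_%02d", seq_len(n_plants)),
        flies_per_flowerhead = dens * share / heads,
        flowerheads_per_m2 = heads
      )
    }
  }
  list(records = do.call(rbind, recs),
       sites = data.frame(site_id = site_ids, density_mc = d_mc,
                          density_cn = d_cn, color_code = color),
       params = list(n_sites = n_sites, beta0 = beta0, beta1 = beta1,
                     zero_prob = zero_prob, meanlog = meanlog, sdlog = sdlog,
                     cn_scale = cn_scale, separation_mode = separation_mode,
                     seed = seed))
}

#' Generate synthetic flower-choice sequences
#'
#' Simulates the cage choice experiment: each fly carries a latent
#' preference for orange drawn from a Beta distribution with the species'
#' marginal preference as its mean, and makes a sequence of independent
#' Bernoulli choices given that preference. Beta mixing induces an
#' exchangeable within-fly correlation `alpha = 1 / (concentration + 1)`,
#' exactly the working structure the GEE assumes. Sequence lengths follow
#' a geometric law truncated to [1, 20] (median near 5); each choice is
#' made on a randomly assigned soil.
#'
#' @param n_flies Named vector of flies per species (defaults to the
#'   study's Ursinia experiment: 47 `M_capensis`, 20 `C_nigripes`).
#' @param pref_orange Named marginal probabilities of choosing orange
#'   (defaults 0.91 for `M_capensis`, 0.20 for `C_nigripes`, i.e., an 80%
#'   white preference).
#' @param concentration Beta concentration `a + b` (default 10, giving
#'   within-fly correlation ~0.09). `Inf` gives independent choices.
#' @param genus_pair `"Ursinia"` or `"Dimorphotheca"` label.
#' @param phase Phase label for every trial (default `"pre"`).
#' @param geom_prob Success probability of the geometric sequence-length
#'   law (default 0.13, median length 5 after truncation at 20).
#' @param seed Integer seed.
#' @param fly_id_offset Offset for fly numbering (so phases/genera can be
#'   given distinct or matching ids).
#' @return Data frame of choice trials: `fly_id`, `fly_species`,
#'   `genus_pair`, `phase`, `choice_order`, `flower_color`, `soil`.
#' @export
gen_choices <- function(n_flies = c(M_capensis = 47, C_nigripes = 20),
                        pref_orange = c(M_capensis = 0.91, C_nigripes = 0.20),
                        concentration = 10, genus_pair = "Ursinia",
                        phase = "pre", geom_prob = 0.13, seed = 1,
                        fly_id_offset = 0) {
  stopifnot(all(n_flies >= 2), all(pref_orange > 0 & pref_orange < 1),
            concentration > 0)
  set.seed(as.integer(seed))
  out <- list()
  fly_counter <- fly_id_offset
  for (sp in names(n_flies)) {
    m <- pref_orange[[sp]]
    for (f in seq_len(n_flies[[sp]])) {
      fly_counter <- fly_counter + 1
      p_i <- if (is.finite(concentration)) {
        stats::rbeta(1, m * concentration, (1 - m) * concentration)
      } else m
      len <- min(stats::rgeom(1, geom_prob) + 1, 20)
      choices <- stats::rbinom(len, 1, p_i)
      out[[length(out) + 1]] <- data.frame(
        fly_id = sprintf("fly_%04d", fly_counter),
        fly_species = sp,
        genus_pair = genus_pair,
        phase = phase,
        choice_order = seq_len(len),
        flower_color = ifelse(choices == 1, "orange", "white"),
        soil = ifelse(stats::runif(len) < 0.5, "red", "pale")
      )
    }
  }
  do.call(rbind, out)
}
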