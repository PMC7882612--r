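#!/usr/bin/env Rscript
# Stage 0: generate the synthetic study data every later stage consumes.
# Writes reflectance spectra, the landscape survey, and choice-trial tables
# under results/data/.

suppressMessages(library(daisyfly))
seed <- 20260925
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

grid <- wl_grid(300, 700, 1)

# five replicate capitula per focal species, plus soil backgrounds
kinds <- c(D_sinuata = "orange_flower", U_cakilefolia = "orange_flower",
           D_pluvialis = "white_flower", U_speciosa = "white_flower")
# the two orange species differ in UV-peak position and intensity
uv_tweaks <- list(D_sinuata = list(uv_center = 350, uv_amp = 0.22),
                  U_cakilefolia = list(uv_center = 336, uv_amp = 0.15))
spectra <- list()
for (sp in names(kinds)) {
  for (i in 1:5) {
    ovr <- if (sp %in% names(uv_tweaks)) uv_tweaks[[sp]] else list()
    spectra[[paste(sp, i, sep = "_")]] <-
      gen_spectrum(kinds[[sp]], grid, seed = seed + length(spectra),
                   overrides = ovr, label = paste(sp, i, sep = "_"))
  }
}
for (soil in c("pale_soil", "red_soil")) {
  for (i in 1:5) {
    spectra[[paste(soil, i, sep = "_")]] <-
      gen_spectrum(soil, grid, seed = seed + length(spectra),
                   label = paste(soil, i, sep = "_"))
  }
}
write_spectra_csv(spectra, file.path(out, "spectra.csv"))

# landscape survey: 54 sites, logistic colour-density link
L <- gen_landscape(n_sites = 54, seed = seed)
write.csv(L$records, file.path(out, "survey_records.csv"), row.names = FALSE)
write.csv(L$sites, file.path(out, "site_summary.csv"), row.names = FALSE)

# choice experiments, both genus pairs, at the reported fly counts
ch_urs <- gen_choices(n_flies = c(M_capensis = 47, C_nigripes = 20),
                      genus_pair = "Ursinia", seed = seed + 1)
ch_dim <- gen_choices(n_flies = c(M_capensis = 26, C_nigripes = 26),
                      genus_pair = "Dimorphotheca", seed = seed + 2,
                      fly_id_offset = 1000)
write.csv(rbind(ch_urs, ch_dim), file.path(out, "choice_trials.csv"),
          row.names = FALSE)

# conditioning experiment: preferences unchanged after conditioning
pre <- gen_choices(n_flies = c(M_capensis = 20),
                   pref_orange = c(M_capensis = 0.91),
                   phase = "pre", seed = seed + 3, fly_id_offset = 2000)
post <- gen_choices(n_flies = c(M_capensis = 20),
                    pref_orange = c(M_capensis = 0.91),
                    phase = "post_1h", seed = seed + 4, fly_id_offset = 2100)
write.csv(rbind(pre, post), file.path(out, "conditioning_trials.csv"),
          row.names = FALSE)

cat("Wrote", length(spectra), "spectra,", nrow(L$records), "survey records,",
    nrow(ch_urs) + nrow(ch_dim), "choices, and",
    nrow(pre) + nrow(post), "conditioning choices to", out, "\n")
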