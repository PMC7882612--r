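#!/usr/bin/env Rscript
# Stage 3: do the two fly pollinators have divergent flower colour
# preferences? GEE per genus pair with exchangeable working correlation
# and jackknife variances, estimated marginal preferences, first-choice
# soil tests, and the conditioning contrast.

suppressMessages(library(daisyfly))
dir.create("results", showWarnings = FALSE)
trials <- read.csv("results/data/choice_trials.csv")
cond <- read.csv("results/data/conditioning_trials.csv")

report <- list()
for (genus in c("Ursinia", "Dimorphotheca")) {
  tr <- trials[trials$genus_pair == genus, ]
  des <- build_design(tr, formula = c("species", "soil", "species:soil"),
                      require_both_soils = TRUE)
  fit <- gee_fit(des$y, des$x, des$cluster)
  w_sp <- wald_test(fit, "^speciesM_capensis$")
  w_soil <- wald_test(fit, "^soilred$")
  w_int <- wald_test(fit, "^speciesM_capensis:soilred$")
  em_mc <- gee_emmeans(fit, des, at = list(species = "M_capensis"))
  em_cn <- gee_emmeans(fit, des, at = list(species = "C_nigripes"))
  cat(sprintf("\n%s pair: %d flies, %d choices (excluded %d flies not using both soils)\n",
              genus, fit$n_clusters, fit$n_obs, length(des$excluded)))
  cat(sprintf("  species     Wald = %6.2f, p = %.2g\n", w_sp$wald, w_sp$p))
  cat(sprintf("  soil        Wald = %6.2f, p = %.2f\n", w_soil$wald, w_soil$p))
  cat(sprintf("  interaction Wald = %6.2f, p = %.2f\n", w_int$wald, w_int$p))
  cat(sprintf("  P(orange): M_capensis %.2f [%.2f, %.2f]; C_nigripes %.2f [%.2f, %.2f]\n",
              em_mc$estimate, em_mc$lower, em_mc$upper,
              em_cn$estimate, em_cn$lower, em_cn$upper))
  report[[genus]] <- list(
    n_flies = fit$n_clusters, n_choices = fit$n_obs,
    excluded = des$excluded, alpha = fit$alpha,
    coefficients = as.list(fit$coefficients),
    wald = list(species = w_sp, soil = w_soil, interaction = w_int),
    emm = list(M_capensis = em_mc, C_nigripes = em_cn))
}

# first-choice detectability tests across soils (counts from the
# synthetic first-choice experiment: white flowers easier to find on red
# soil for C_nigripes, no soil effect for M_capensis)
set.seed(20260925)
red_cn <- rbinom(1, 45, 0.73)
red_mc <- rbinom(1, 44, 0.5)
chi_cn <- first_choice_chisq(red_cn, 45 - red_cn)
chi_mc <- first_choice_chisq(red_mc, 44 - red_mc)
cat(sprintf("\nFirst choices across soils:\n  C_nigripes %d red / %d pale: chi2 = %.2f, p = %.3f\n  M_capensis %d red / %d pale: chi2 = %.2f, p = %.2f\n",
            red_cn, 45 - red_cn, chi_cn$chisq, chi_cn$p,
            red_mc, 44 - red_mc, chi_mc$chisq, chi_mc$p))
report$first_choice <- list(C_nigripes = chi_cn, M_capensis = chi_mc)

# conditioning on the non-preferred colour: did preferences move?
cc <- conditioning_contrast(cond)
cat(sprintf("\nConditioning (M_capensis, 1 h on white): phase Wald = %.2f, p = %.2f -> %s\n",
            cc$phase_test$wald, cc$phase_test$p,
            if (cc$phase_test$p < 0.05) "preference altered"
            else "no detectable change"))
report$conditioning <- list(phase_wald = cc$phase_test)

jsonlite::write_json(report, "results/choice_fits.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nwrote results/choice_fits.json\n")
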