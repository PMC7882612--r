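# daisyfly

Analysis toolkit for landscape-scale structuring of flower colour in
annual daisy communities by their fly pollinators. The Namaqualand
(South Africa) spring displays are orange- or white-dominated, and the
turnover tracks two bee-fly pollinators with largely non-overlapping
ranges. `daisyfly` implements the three computational stages that test
whether this is a pollinator-driven mosaic, plus a synthetic-data
generator so the whole pipeline runs and is verified without any field
data:

1. **Fly-vision colorimetry.** Photoreceptor quantum catches
   `Q_r = ∫ R(λ) I(λ) S_r(λ) dλ`, von Kries adaptation against the soil
   background, and the categorical fly colour-opponency plane
   `x = e(R7p) − e(R8p)`, `y = e(R7y) − e(R8y)` with excitation
   `e = q/(q+1)`. Detectability = distance from the origin vs the
   syrphid minimum-discrimination thresholds (0.021 in p−y−, 0.059 in
   p+y−); discriminability = distance between species centroids;
   Welch's *t* across soils.
2. **Pollinator mosaic.** Site fly densities (individuals m⁻²) rebuilt
   from survey records, then logistic regression of binary site colour
   (orange = 1) on density — ordinary MLE with an explicit separation
   flag, and Firth's bias-reduced fit `ℓ*(β) = ℓ(β) + ½ log det I(β)`
   with penalised LR tests, which stays finite under the complete
   separation the white-community fly produces.
3. **Choice experiments.** Binomial GEE (logit link, exchangeable
   working correlation, leave-one-cluster-out jackknife variances) for
   clustered per-fly choice sequences, Wald tests, estimated marginal
   preference probabilities, first-choice soil chi-square tests, and
   conditioning contrasts.

The methods, assumptions, and generator design are documented in
`vignettes/daisyfly-methods.Rmd`.

## Worked example

```r
library(daisyfly)

grid <- wl_grid(300, 700, 1)
rec  <- receptor_set(grid)          # stand-in nomogram receptors
ill  <- d65_illuminant(grid)        # photon-unit D65

orange <- gen_spectrum("orange_flower", grid, seed = 1)
white  <- gen_spectrum("white_flower",  grid, seed = 2)
soil   <- gen_spectrum("pale_soil",     grid, seed = 3)

q_bg <- quantum_catch(soil, ill, rec)
(p_o <- troje_point(quantum_catch(orange, ill, rec), q_bg))
#> <vision_point> (0.3263, 0.0750) p+y+, dist 0.3348
(p_w <- troje_point(quantum_catch(white, ill, rec), q_bg))
#> <vision_point> (-0.5326, -0.4700) p-y-, dist 0.7103
detectability_verdict(p_w)
#> [1] "detectable"
```

The orange and white flowers fall in different quadrants of the
opponency plane — i.e. the model calls them categorically
distinguishable to a fly — and the white flower's distance from the
origin (0.71) is far above the 0.021 threshold of its p−y− quadrant, so
it is detectable against this soil.

```r
trials <- gen_choices(seed = 42)    # 47 + 20 flies, Ursinia-pair defaults
des <- build_design(trials)
fit <- gee_fit(des$y, des$x, des$cluster)
wald_test(fit, "speciesM_capensis")$wald
#> [1] 68.6756
em <- gee_emmeans(fit, des, at = list(species = "M_capensis"))
round(c(pref = em$estimate, lo = em$lower, hi = em$upper), 3)
#>  pref    lo    hi
#> 0.868 0.802 0.914
```

The two fly species differ strongly in colour choice (Wald χ² = 68.7 on
1 df), and the marginal probability that *M. capensis* chooses orange is
0.87 (95 % CI 0.80–0.91), recovering the generating preference of 0.91
within sampling error.

## The analysis workflow

The `analysis/` scripts run the three stages as a narrative pipeline
over generated data, writing tables under `results/`:

```sh
Rscript analysis/01_generate_data.R      # spectra, surveys, choice trials
Rscript analysis/02_vision_model.R       # opponency points, centroids, Welch tests
Rscript analysis/03_pollinator_mosaic.R  # density -> colour logistic fits
Rscript analysis/04_choice_experiments.R # GEE preferences, conditioning
```

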