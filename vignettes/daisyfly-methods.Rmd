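---
title: "Modelling fly colour vision and pollinator mosaics in daisy communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fly colour vision and pollinator mosaics in daisy communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daisyfly)
```

# The scientific problem

Spring mass-flowering daisy communities in Namaqualand (South Africa) are
either orange- or white-dominated, and the turnover tracks the largely
non-overlapping distributions of two bee-fly pollinators: *Megapalpus
capensis* in orange communities and *Corsomyza nigripes* in white ones.
Three questions structure the analysis this package implements:

1. **Vision** — are orange and white ray florets detectable against their
   soil backgrounds, and distinguishable from each other, to a fly visual
   system?
2. **Mosaic** — is the flower colour of a site predicted by the local
   density of each fly species?
3. **Preference** — do the two flies show divergent, stable colour
   preferences in choice experiments?

The package provides each stage as tested functions plus a synthetic-data
generator, so the full pipeline runs end to end without field data (the
original spectra, images, and visit records are unpublished).

# Stage 1: the categorical fly colour-opponency model

## Quantum catches

A photoreceptor's signal from a stimulus with reflectance $R(\lambda)$
under illuminant $I(\lambda)$ is the quantum catch

$$Q_r = \int R(\lambda)\, I(\lambda)\, S_r(\lambda)\, d\lambda,$$

with $S_r$ the receptor's spectral sensitivity. `quantum_catch()`
evaluates this by the trapezoidal rule on a common wavelength grid. The
default grid is 300–700 nm at 1 nm: it spans both the UV band (where the
orange daisies carry a secondary reflectance peak near 330–370 nm) and
the visible band, and at 1 nm the trapezoid error for smooth floral
spectra is far below 0.1 % (verified in the test suite against a 0.1 nm
brute-force oracle).

The bundled illuminant is standard daylight D65, by default converted
from relative spectral power to relative photon flux (multiplication by
$\lambda$, then renormalisation) because photoreceptors count photons.
The convention is a config switch (`photon_units`) since published fly
modelling work is not always explicit about it; note the von Kries step
below removes any *overall* scaling, but not the spectral reweighting.

## Receptor sensitivities

The model uses the two R7/R8 photoreceptor pairs of the pale and yellow
ommatidia (R7p, R7y, R8p, R8y). Measured sensitivities for the relevant
flies are not available — bombyliid receptors are unmeasured, and the
published syrphid (*Eristalis tenax*) curves used in the original
modelling are not printed anywhere we can bundle. `receptor_set()`
therefore defaults to A1 visual-pigment nomogram templates (alpha band
only, peak-aligned) at stand-in peaks of 330, 350, 460 and 530 nm — a UV,
UV-blue, blue and green quartet consistent with the cyclorrhaphan R7p/
R7y/R8p/R8y pattern. These defaults are deliberately exposed and
overridable: any conclusions that depend on exact peak positions should
be checked against tabulated curves supplied via CSV.

## Opponency coordinates

`troje_point()` implements the categorical colour-opponency model.
Stimulus catches are first von Kries–adapted against the background of
the same image, $q_r = Q_r^{\text{stim}} / Q_r^{\text{bg}}$, then mapped
to excitations $e_r = q_r / (q_r + 1)$, and the plane coordinates are the
two opponent differences

$$x = e_{R7p} - e_{R8p}, \qquad y = e_{R7y} - e_{R8y}.$$

The hyperbolic excitation is a design choice the source analyses leave
implicit. We adopt it because it (a) maps the adapting background to the
origin *exactly* — required for "distance from the origin" to mean
chromatic contrast against the background, and for the adaptation
fixed-point property the acceptance tests assert at $10^{-12}$; and
(b) bounds both coordinates in $(-1, 1)$. A `linear` transform is
available for sensitivity analysis.

The four quadrants (p±y±) are the model's distinguishable colour
categories. `classify_quadrant()` labels points, with an explicit
`"boundary"` label for coordinates within $10^{-12}$ of an axis so that
verdicts cannot flip on numerical noise.

## Detectability and discriminability

*Detectability* of a stimulus is its Euclidean distance from the origin,
compared with experimentally determined minimum discrimination distances
for syrphid flies: 0.021 in the p−y− quadrant and 0.059 in p+y−. Those
are the only two quadrants with measured thresholds, so
`detectability_verdict()` returns `"unknown"` elsewhere rather than
extrapolating; the default `threshold_map()` carries exactly those two
entries. The comparison uses a ≥ rule at the threshold.
*Discriminability* of two species is the distance between their cloud
centroids (`centroid_distance()`); applying the same thresholds to
centroid separations is a guide only, since the thresholds were measured
for contrast-to-background, not colour-to-colour discrimination.

Per-image points average quantum catches over the measured regions
*before* the excitation transform (`region_mean_point()`), matching the
described workflow of averaging catches over five regions per image.

Welch's unequal-variance $t$ (`welch_t()`) compares a species'
distances-from-origin across soils; it is two-sided by default with a
`one_sided` flag for the directional native-soil question.

# Stage 2: pollinator mosaic

Site-level fly density (individuals m⁻²) is rebuilt from survey records
as $\sum_{\text{plants}} (\text{flies per flowerhead}) \times
(\text{flowerheads per m}^2)$ (`fly_density_per_m2()`). Site flower
colour is coded 1 = orange, 0 = white (`site_color_code()`), with a hard
error on mixed sites because the landscape data contain none.

Colour is regressed on density with two fits:

* `logistic_fit_mle()` — ordinary logistic regression via IRLS, with an
  explicit *separation* flag (non-convergence, runaway coefficients, or
  fitted probabilities pinned at 0/1) instead of silently divergent
  estimates.
* `logistic_fit_firth()` — Firth's bias-reduced fit, maximising the
  Jeffreys-penalised likelihood
  $\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det I(\beta)$
  by Newton steps on the modified score
  $U^*_j = \sum_i (y_i - \pi_i + h_i(\tfrac12 - \pi_i)) x_{ij}$, with
  step-halving. Estimates stay finite under complete separation — the
  regime the white-community fly produces, since orange sites occur only
  where it is absent. Inference defaults to penalised likelihood-ratio
  tests per slope (profile fit with the slope pinned at zero, using the
  full-model information in the penalty), with Wald statistics secondary.

Numerical choices: score-norm tolerance $10^{-8}$, at most 100
iterations, step-halving down to $\lambda = 10^{-4}$. The density
covariate enters untransformed (any transformation can be applied by the
caller); sites lacking the focal species are excluded upstream. The
`df = n - 1` residual degrees of freedom are reported for display parity
with field reports, but tests use the standard references (normal for
Wald $z$, $\chi^2_1$ for LR).

# Stage 3: choice experiments

Each fly makes a short ordered sequence of flower choices, so choices are
clustered within flies. The marginal model is a binomial GEE with logit
link (`gee_fit()`): response 1 = orange chosen; predictors fly species,
soil, and their interaction (reference levels `C_nigripes`, `pale`,
`pre`, fixed so signs are reproducible); exchangeable working
correlation, matching the assumption that a fly's sequential choices are
equally correlated.

Estimation is Liang–Zeger: start at the independence GLM; estimate the
exchangeable $\alpha$ by moment matching on within-cluster Pearson
residual cross-products (dispersion $\phi$ fixed at 1 for binary data,
estimable on request); Fisher-scoring updates of $\beta$. An $\alpha$
outside its admissible range $(-1/(n_{\max}-1), 1)$ is clipped with a
warning. Variances are leave-one-cluster-out jackknife: the default is
the one-step (influence-function) approximation
$\hat\beta_{(k)} \approx \hat\beta + (H - H_k)^{-1} U_k$, with the
full-refit jackknife behind `jackknife = "full"` as a cross-check; the
covariance is $\frac{K-p}{K} \sum_k (\hat\beta_{(k)} - \bar\beta_{(\cdot)})
(\hat\beta_{(k)} - \bar\beta_{(\cdot)})'$. Flies that never visited
flowers on both soils can be excluded at design-build time
(`require_both_soils`), mirroring the experimental protocol; exclusion
happens before $\alpha$ estimation.

`wald_test()` gives $\chi^2$ tests of single coefficients or joint
contrasts with the jackknife covariance; `gee_emmeans()` returns
estimated marginal means on the probability scale (link-scale averaging
over the unfixed factors of an equally weighted reference grid, CI built
on the link scale so endpoints stay inside $(0,1)$).
`first_choice_chisq()` is the 1-df goodness-of-fit test
$(a-b)^2/(a+b)$ for first choices split across soils, and
`conditioning_contrast()` wraps the phase-term Wald test for the
conditioning experiments. The two genus pairs (*Dimorphotheca*,
*Ursinia*) are analysed separately, as in the experiments; pooling is
possible but not the default.

# The synthetic-data generator

Because none of the field data are deposited, the package generates data
with the statistical structure each analysis assumes. The generator
defaults *are* the study conditions; they are set once from the reported
design and not adjusted per analysis.

* **Spectra** (`gen_spectrum()`): sigmoidal base + UV Gaussian +
  truncated Gaussian noise, clipped to [0, 1]. White daisies: bright flat
  plateau above ~400 nm, dark UV. Orange daisies: dark below ~550 nm,
  bright above, secondary UV peak near 350 nm whose position/intensity
  can be shifted per species. Pale granite soil: moderate, fairly flat;
  red marine sand: dark at short wavelengths rising toward the red.
* **Landscape** (`gen_landscape()`): 54 sites; the orange-community
  fly's density is zero-inflated log-normal (30 % absences,
  log-normal(log 0.35, 0.8)) so survey-scale maxima near 1.7 m⁻² occur;
  the white-community fly is scaled ×2.2 (maxima near 3.7 m⁻²) and
  present mainly where the first is absent. Site colour is Bernoulli
  with logit $= \beta_0 + \beta_1 d$, defaults $(-2, 3)$ — a strong but
  estimable association at $n = 54$. `separation_mode` instead makes
  colour deterministic in the white-community fly's absence, reproducing
  complete separation. Per-site densities are factored into plant-level
  records whose product-sum reconstructs the drawn density to machine
  precision.
* **Choices** (`gen_choices()`): per fly a latent preference
  $p_i \sim \mathrm{Beta}$ with the species' marginal preference as mean
  (defaults 0.91 orange for *M. capensis*, 0.20 — i.e. 80 % white — for
  *C. nigripes*, at 47/20 flies as in the *Ursinia* experiment) and
  concentration 10, giving exchangeable within-fly correlation
  $\alpha = 1/(a+b+1) = 1/11$ in closed form — exactly the GEE's working
  structure, which makes the generator its own oracle. Sequence lengths
  are geometric (p = 0.13), truncated to [1, 20], median ≈ 5; soils are
  assigned per choice with probability ½.

## What the generator does and does not emulate

It reproduces the *statistical* structure (clustered binary choices with
exchangeable correlation, zero-inflated density gradients, complete
separation, UV-structured reflectance) at the reported sample sizes. It
does not attempt photometric realism: the synthetic soil and flower
spectra are stylised, so synthetic white flowers contrast with the soils
far more strongly than the measured ones did (where white-flower
detectability was only marginal), and the per-choice random soil
assignment yields more single-soil flies than the real arenas did.
Passing tests therefore demonstrate correctness of the estimators and
the qualitative reproduction of the system's structure (orange and white
in different quadrants, separation handled, preferences recovered), not
quantitative agreement with the unpublished field measurements.

# Problem sizes and runtime choices

The test suite and acceptance checks use the study's own scales: 54
sites, 47/20 and 26/26 flies, 5 replicate spectra per species, sequences
of median 5 truncated at 20. Simulation-based calibration checks use 200
replicates for coverage/recovery and 500 for type-I error — enough for
the asserted bands (e.g. rejection rate in [0.02, 0.09]) to be stable
across seeds while keeping a full run to about a minute.

# Known limitations

* Receptor peaks are stand-ins; quadrant assignments can shift with the
  true sensitivities.
* No receptor-noise (RNL) model, no achromatic channel, no alternative
  (bee) colour spaces, and no inter-ommatidial opponency — the model is
  deliberately the categorical intra-ommatidial one.
* The GEE is marginal; no fly-level random-effects (conditional) model.
* No spatial autocorrelation in the landscape regression.
* The exact jackknife variant of the original geepack-based analysis is
  not derivable from its description; the one-step leave-one-cluster-out
  estimator implemented here matches the "approximate jackknife" phrase
  and is validated against full refits in the tests.
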