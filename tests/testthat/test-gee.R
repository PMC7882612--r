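make_trials <- function(...) gen_choices(..., seed = 101)

test_that("design building expands choices, codes the response, and validates levels", {
  tr <- data.frame(
    fly_id = rep(c("f1", "f2"), c(5, 3)),
    fly_species = rep(c("M_capensis", "C_nigripes"), c(5, 3)),
    genus_pair = "Ursinia", phase = "pre",
    choice_order = c(1:5, 1:3),
    flower_color = c(rep("orange", 5), rep("white", 3)),
    soil = c("red", "pale", "red", "red", "pale", "pale", "pale", "red")
  )
  des <- build_design(tr)
  expect_length(des$y, 8)
  expect_equal(sum(des$cluster == "f1"), 5)
  expect_equal(des$y, c(rep(1, 5), rep(0, 3)))
  # reference levels: C_nigripes, pale
  expect_true(all(c("speciesM_capensis", "soilred",
                    "speciesM_capensis:soilred") %in% colnames(des$x)))

  bad <- tr; bad$flower_color[1] <- "blue"
  expect_error(build_design(bad), "input error")
  expect_error(build_design(tr, formula = "weather"), "unknown predictor")
})

test_that("flies that never visited both soils are excluded when required", {
  tr <- data.frame(
    fly_id = rep(c("f1", "f2", "f3", "f4"), each = 4),
    fly_species = "M_capensis", genus_pair = "Ursinia", phase = "pre",
    choice_order = rep(1:4, 4),
    flower_color = rep(c("orange", "white"), 8),
    soil = c(rep("red", 4), rep(c("red", "pale"), 2), rep("pale", 4),
             rep(c("pale", "red"), 2))
  )
  expect_message(des <- build_design(tr, formula = "soil",
                                     require_both_soils = TRUE),
                 "excluded")
  expect_setequal(des$excluded, c("f1", "f3"))
  expect_error(build_design(tr[tr$fly_id == "f1", ]), ">= 2 flies")
})

test_that("GEE collapses to the independence logistic MLE when clusters have size 1", {
  set.seed(31)
  n <- 120
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(0.2 + 0.7 * x[, 1] - 0.5 * x[, 2]))
  g <- gee_fit(y, x, cluster = seq_len(n))
  ref <- glm(y ~ x, family = binomial)
  expect_lt(max(abs(g$coefficients - coef(ref))), 1e-8)
  expect_equal(g$alpha, 0)
})

test_that("fixing the working correlation at zero reproduces independence coefficients", {
  tr <- make_trials()
  des <- build_design(tr)
  g0 <- gee_fit(des$y, des$x, des$cluster, alpha = 0)
  ref <- glm(des$y ~ des$x, family = binomial)
  expect_lt(max(abs(g0$coefficients - coef(ref))), 1e-7)
})

test_that("estimated alpha tracks the beta-mixing construction and vanishes without mixing", {
  # beta-mixed choices: alpha ~ 1 / (concentration + 1)
  tr <- gen_choices(n_flies = c(M_capensis = 400),
                    pref_orange = c(M_capensis = 0.6),
                    concentration = 10, seed = 41)
  des <- build_design(tr, formula = character(0))
  fit <- gee_fit(des$y, NULL, des$cluster)
  expect_lt(abs(fit$alpha - 1 / 11), 0.04)

  # infinite concentration: i.i.d. choices, alpha near 0
  tr0 <- gen_choices(n_flies = c(M_capensis = 400),
                     pref_orange = c(M_capensis = 0.6),
                     concentration = Inf, seed = 42)
  des0 <- build_design(tr0, formula = character(0))
  fit0 <- gee_fit(des0$y, NULL, des0$cluster)
  expect_lt(abs(fit0$alpha), 0.03)
})

test_that("jackknife covariance is symmetric PSD and both variants agree", {
  tr <- make_trials()
  des <- build_design(tr)
  f1 <- gee_fit(des$y, des$x, des$cluster, jackknife = "one_step")
  expect_equal(f1$vcov, t(f1$vcov))
  ev <- eigen(f1$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))

  f2 <- gee_fit(des$y, des$x, des$cluster, jackknife = "full")
  se1 <- sqrt(diag(f1$vcov)); se2 <- sqrt(diag(f2$vcov))
  expect_lt(max(abs(se1 - se2) / se2), 0.25)
})

test_that("Wald tests: null value, 1-df identity, covariate-rescale invariance", {
  tr <- make_trials()
  des <- build_design(tr)
  fit <- gee_fit(des$y, des$x, des$cluster)
  w <- wald_test(fit, "speciesM_capensis")
  se <- sqrt(diag(fit$vcov))["speciesM_capensis"]
  expect_equal(w$wald,
               unname((fit$coefficients["speciesM_capensis"] / se)^2))
  expect_equal(w$df, 1)

  # coefficient forced to zero via contrast on a null direction
  L0 <- matrix(0, 1, length(fit$coefficients))
  expect_error(wald_test(fit, L0), "rank error")

  # rescaling a continuous covariate leaves its Wald statistic unchanged
  set.seed(51)
  n <- 150; cl <- rep(1:50, each = 3)
  u <- rep(rnorm(50, 0, 0.8), each = 3)
  z <- rnorm(n)
  yy <- rbinom(n, 1, plogis(0.2 + 0.6 * z + u))
  fa <- gee_fit(yy, cbind(z = z), cl)
  fb <- gee_fit(yy, cbind(z = 10 * z), cl)
  expect_equal(wald_test(fa, "z")$wald, wald_test(fb, "z")$wald,
               tolerance = 1e-6)
})

test_that("marginal means: inverse-logit identities and CIs inside (0,1)", {
  # intercept-only at beta0 = 0 -> EMM one half; perfectly alternating
  # outcomes push the moment alpha below its admissible bound, which must
  # be clipped with a warning
  y <- rep(c(0, 1), 30)
  cl <- rep(1:30, each = 2)
  expect_warning(fit <- gee_fit(y, NULL, cl), "clipped")
  des <- list(terms = character(0), xlevels = list())
  em <- gee_emmeans(fit, des)
  expect_equal(em$estimate, 0.5, tolerance = 1e-8)
  expect_true(em$lower > 0 && em$upper < 1 && em$lower <= em$estimate &&
                em$estimate <= em$upper)

  # equal cluster sizes, intercept only: EMM equals the raw proportion
  tr <- gen_choices(n_flies = c(M_capensis = 30),
                    pref_orange = c(M_capensis = 0.7),
                    concentration = 5, geom_prob = 1e-9, seed = 61)  # all length 20
  des2 <- build_design(tr, formula = character(0))
  fit2 <- gee_fit(des2$y, NULL, des2$cluster)
  em2 <- gee_emmeans(fit2, des2)
  expect_equal(em2$estimate, mean(des2$y), tolerance = 1e-7)

  # EMM at the reference combination equals inverse-logit of the intercept
  tr3 <- make_trials()
  des3 <- build_design(tr3)
  fit3 <- gee_fit(des3$y, des3$x, des3$cluster)
  em3 <- gee_emmeans(fit3, des3,
                     at = list(species = "C_nigripes", soil = "pale"))
  expect_equal(em3$estimate,
               unname(plogis(fit3$coefficients["(Intercept)"])))
  expect_error(gee_emmeans(fit3, des3, at = list(species = "E_tenax")),
               "input error")
})

test_that("first-choice chi-square follows the (a-b)^2/n closed form", {
  expect_equal(first_choice_chisq(22, 22)$chisq, 0)
  expect_equal(first_choice_chisq(22, 22)$p, 1)
  r <- first_choice_chisq(30, 14)
  expect_equal(r$chisq, 256 / 44)
  ref <- chisq.test(c(30, 14), p = c(0.5, 0.5))
  expect_equal(r$chisq, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  expect_equal(first_choice_chisq(9, 0)$chisq, 9)
  expect_error(first_choice_chisq(-1, 3), "input error")
  expect_error(first_choice_chisq(0, 0), "input error")
})

test_that("conditioning contrast is null when post duplicates pre, errors on one phase", {
  pre <- gen_choices(n_flies = c(M_capensis = 15),
                     pref_orange = c(M_capensis = 0.8), seed = 71)
  post <- pre
  post$phase <- "post_1h"
  both <- rbind(pre, post)
  cc <- conditioning_contrast(both)
  expect_lt(abs(cc$fit$coefficients["phasepost_1h"]), 1e-8)
  expect_error(conditioning_contrast(pre), "input error")
})

test_that("choice generator matches its marginal law and truncation", {
  tr <- gen_choices(n_flies = c(M_capensis = 2000),
                    pref_orange = c(M_capensis = 0.91),
                    concentration = 10, seed = 81)
  expect_lt(abs(mean(tr$flower_color == "orange") - 0.91), 0.01)
  lens <- tapply(tr$choice_order, tr$fly_id, max)
  expect_true(all(lens <= 20) && all(lens >= 1))
  expect_identical(gen_choices(seed = 82), gen_choices(seed = 82))
})

test_that("marginal preferences are recovered at the study's fly counts", {
  # 47 M_capensis (pref 0.91) and 20 C_nigripes (pref 0.20 orange):
  # mean EMM over replicates within 0.05 of the generating value
  ems <- vapply(1:20, function(i) {
    tr <- gen_choices(seed = 900 + i)
    des <- build_design(tr, formula = "species")
    fit <- gee_fit(des$y, des$x, des$cluster)
    c(mc = gee_emmeans(fit, des, at = list(species = "M_capensis"))$estimate,
      cn = gee_emmeans(fit, des, at = list(species = "C_nigripes"))$estimate)
  }, numeric(2))
  expect_lt(abs(mean(ems["mc", ]) - 0.91), 0.05)
  expect_lt(abs(mean(ems["cn", ]) - 0.20), 0.05)
})

test_that("the conditioning contrast detects a flipped preference and not an unchanged one", {
  flips <- vapply(1:10, function(i) {
    pre <- gen_choices(n_flies = c(M_capensis = 40),
                       pref_orange = c(M_capensis = 0.9),
                       phase = "pre", seed = 600 + i)
    post <- gen_choices(n_flies = c(M_capensis = 40),
                        pref_orange = c(M_capensis = 0.1),
                        phase = "post_1h", seed = 700 + i,
                        fly_id_offset = 500)
    conditioning_contrast(rbind(pre, post))$phase_test$p
  }, numeric(1))
  expect_true(all(flips < 0.05))

  # unchanged preference: p should usually be non-significant
  nulls <- vapply(1:10, function(i) {
    pre <- gen_choices(n_flies = c(M_capensis = 40),
                       pref_orange = c(M_capensis = 0.9),
                       phase = "pre", seed = 800 + i)
    post <- gen_choices(n_flies = c(M_capensis = 40),
                        pref_orange = c(M_capensis = 0.9),
                        phase = "post_1h", seed = 850 + i,
                        fly_id_offset = 500)
    conditioning_contrast(rbind(pre, post))$phase_test$p
  }, numeric(1))
  expect_gte(mean(nulls > 0.05), 0.8)
})
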