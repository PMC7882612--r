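test_that("quantum catches: zero stimulus, constant integrand, grid mismatch", {
  g <- wl_grid(300, 700, 1)
  ones <- spectrum(g, rep(1, 401), "illuminant")
  flat_rec <- receptor_set(g, sensitivities = list(
    R7p = spectrum(g, rep(1, 401), "sensitivity"),
    R7y = spectrum(g, rep(1, 401), "sensitivity"),
    R8p = spectrum(g, rep(1, 401), "sensitivity"),
    R8y = spectrum(g, rep(1, 401), "sensitivity")))
  zero <- spectrum(g, rep(0, 401), "reflectance")
  expect_true(all(quantum_catch(zero, ones, flat_rec) == 0))
  one_r <- spectrum(g, rep(1, 401), "reflectance")
  expect_true(all(abs(quantum_catch(one_r, ones, flat_rec) - 400) < 1e-10))

  g2 <- wl_grid(350, 650, 1)
  s2 <- spectrum(g2, rep(1, 301), "reflectance")
  expect_error(quantum_catch(s2, ones, flat_rec), "grid error")
})

test_that("quantum catches match a 0.1 nm fine-grid integration oracle", {
  g <- wl_grid(300, 700, 1)
  refl <- gaussian_refl_fun(550, 30)
  illum <- smooth_illum_fun()
  rec <- receptor_set(g)
  q <- quantum_catch(spectrum_from_fun(refl, g, "reflectance"),
                     spectrum_from_fun(illum, g, "illuminant"), rec)
  lms <- c(R7p = 330, R7y = 350, R8p = 460, R8y = 530)
  for (k in names(lms)) {
    oracle <- fine_grid_catch(refl, illum, lms[[k]])
    expect_lt(abs(q[[k]] - oracle) / oracle, 0.001)
  }
})

test_that("the opponency transform maps the background to the origin and follows the stated arithmetic", {
  bg <- structure(c(R7p = 2, R7y = 3, R8p = 1.5, R8y = 0.7),
                  class = "quantum_catches")
  p0 <- troje_point(bg, bg)
  expect_identical(p0$x, 0)
  expect_identical(p0$y, 0)
  expect_identical(p0$quadrant, "boundary")

  # closed-form example: q = (3, 1, 1, 3) relative to unit background
  unitbg <- structure(c(R7p = 1, R7y = 1, R8p = 1, R8y = 1),
                      class = "quantum_catches")
  st <- structure(c(R7p = 3, R7y = 1, R8p = 1, R8y = 3),
                  class = "quantum_catches")
  p <- troje_point(st, unitbg)
  expect_equal(p$x, 3 / 4 - 1 / 2)
  expect_equal(p$y, 1 / 2 - 3 / 4)
  expect_identical(p$quadrant, "p+y-")
  expect_equal(p$dist_origin, 0.25 * sqrt(2))

  zerobg <- structure(c(R7p = 1, R7y = 0, R8p = 1, R8y = 1),
                      class = "quantum_catches")
  expect_error(troje_point(st, zerobg), "adaptation error")
})

test_that("opponency coordinates are bounded and invariant to illuminant scale", {
  g <- wl_grid(300, 700, 1)
  rec <- receptor_set(g)
  ill <- d65_illuminant(g)
  set.seed(7)
  for (i in 1:20) {
    refl <- gen_spectrum(sample(c("white_flower", "orange_flower"), 1),
                         g, seed = i)
    bg <- gen_spectrum(sample(c("pale_soil", "red_soil"), 1), g, seed = 100 + i)
    qs <- quantum_catch(refl, ill, rec)
    qb <- quantum_catch(bg, ill, rec)
    p <- troje_point(qs, qb)
    expect_true(abs(p$x) < 1 && abs(p$y) < 1)
    # scaling the illuminant by a positive constant cancels in von Kries
    ill2 <- ill; ill2$values <- ill2$values * 7.3
    p2 <- troje_point(quantum_catch(refl, ill2, rec),
                      quantum_catch(bg, ill2, rec))
    expect_equal(p2$x, p$x, tolerance = 1e-12)
    expect_equal(p2$y, p$y, tolerance = 1e-12)
  }
})

test_that("quadrant classification respects signs and the boundary tolerance", {
  expect_identical(classify_quadrant(0.3, -0.1), "p+y-")
  expect_identical(classify_quadrant(-0.3, 0.1), "p-y+")
  expect_identical(classify_quadrant(0.3, 0.1), "p+y+")
  expect_identical(classify_quadrant(-0.3, -0.1), "p-y-")
  expect_identical(classify_quadrant(0, 0.2), "boundary")
  expect_identical(classify_quadrant(-1e-15, -0.5), "boundary")
  expect_error(classify_quadrant(NaN, 0))
})

test_that("region averaging happens on catches, before the excitation transform", {
  g <- wl_grid(300, 700, 1)
  rec <- receptor_set(g)
  ill <- d65_illuminant(g)
  bg <- gen_spectrum("pale_soil", g, seed = 3)
  r1 <- gen_spectrum("orange_flower", g, seed = 1)
  r2 <- gen_spectrum("orange_flower", g, seed = 2)

  # one region == plain troje_point on that region
  p1 <- region_mean_point(list(r1), bg, ill, rec)
  direct <- troje_point(quantum_catch(r1, ill, rec),
                        quantum_catch(bg, ill, rec))
  expect_equal(p1$x, direct$x)
  expect_equal(p1$y, direct$y)

  # five identical regions == one region
  p5 <- region_mean_point(rep(list(r1), 5), bg, ill, rec)
  expect_equal(p5$x, p1$x)
  expect_equal(p5$y, p1$y)

  # two distinct regions: averaged catches, not averaged excitations
  q1 <- unclass(quantum_catch(r1, ill, rec))
  q2 <- unclass(quantum_catch(r2, ill, rec))
  expected <- troje_point(structure((q1 + q2) / 2, class = "quantum_catches"),
                          quantum_catch(bg, ill, rec))
  p12 <- region_mean_point(list(r1, r2), bg, ill, rec)
  expect_equal(p12$x, expected$x)
  expect_equal(p12$y, expected$y)

  expect_error(region_mean_point(list(), bg, ill, rec), "input error")
})

test_that("centroid distances agree with brute-force recomputation and metric axioms", {
  mk <- function(n, seed) {
    set.seed(seed)
    species_cloud("s", lapply(seq_len(n),
                              function(i) vision_point(runif(1, -0.9, 0.9),
                                                       runif(1, -0.9, 0.9))))
  }
  a <- mk(7, 1); b <- mk(5, 2); c <- mk(9, 3)
  # brute force: mean coordinates then Euclidean distance
  brute <- function(u, v) {
    mu <- c(mean(vapply(u$points, `[[`, numeric(1), "x")),
            mean(vapply(u$points, `[[`, numeric(1), "y")))
    mv <- c(mean(vapply(v$points, `[[`, numeric(1), "x")),
            mean(vapply(v$points, `[[`, numeric(1), "y")))
    sqrt(sum((mu - mv)^2))
  }
  expect_equal(centroid_distance(a, b), brute(a, b))
  expect_equal(centroid_distance(a, b), centroid_distance(b, a))
  expect_identical(centroid_distance(a, a), 0)
  expect_lte(centroid_distance(a, c),
             centroid_distance(a, b) + centroid_distance(b, c) + 1e-12)

  # 3-4-5 triangle
  c1 <- species_cloud("o", list(vision_point(0.1, 0.1), vision_point(-0.1, -0.1)))
  c2 <- species_cloud("w", list(vision_point(0.3, 0.4)))
  expect_equal(centroid_distance(c1, c2), 0.5)
  expect_error(species_cloud("e", list()), "input error")
})

test_that("detectability verdicts apply the quadrant threshold with a >= rule", {
  th <- threshold_map()
  expect_identical(detectability_verdict(vision_point(-0.002, -0.003), th),
                   "not_detectable")   # dist ~0.004 in p-y- vs 0.021
  # boundary convention: distance exactly at the threshold is detectable
  p <- vision_point(0.03, -0.04)
  th_eq <- threshold_map("p+y-" = p$dist_origin)
  expect_identical(detectability_verdict(p, th_eq), "detectable")
  expect_identical(detectability_verdict(vision_point(0.2, -0.2), th),
                   "detectable")
  expect_identical(detectability_verdict(vision_point(0.5, 0.5), th), "unknown")
  expect_identical(detectability_verdict(vision_point(0, 0.5), th), "unknown")
  expect_error(threshold_map("p+y+" = -1))
})

test_that("Welch's t matches the reference implementation and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  w <- welch_t(a, b)
  ref <- t.test(a, b)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p, ref$p.value)

  w2 <- welch_t(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)

  # identical samples degenerate cleanly
  z <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  expect_equal(z$df, 4)

  # one-sided option halves the upper-tail probability for positive t
  ws <- welch_t(b, a, one_sided = TRUE)
  expect_equal(ws$p, welch_t(b, a)$p / 2)

  expect_error(welch_t(1, c(1, 2)), "sample-size error")
  expect_error(welch_t(c(1, 1), c(2, 2)), "constant")
})
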