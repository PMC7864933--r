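test_that("track densities convert to background-corrected fluences", {
  expect_equal(track_to_fluence(100, 0, 100, 0, 2)[["fluence"]], 0)
  expect_equal(track_to_fluence(1000, 0, 100, 0, 0.9)[["fluence"]], 1000)
  expect_equal(track_to_fluence(500, 30, 100, 40, 1)[["sd"]], 50) # 3-4-5
  expect_error(track_to_fluence(10, 0, 0, 0, 0), "calibration")
})

test_that("unfold_sides preserves labels and linearity", {
  g <- energy_grid(c(1, 3))
  ss <- sphere_set(c(0, 5), cd_covered = c(FALSE, FALSE))
  model <- unfolding_model(matrix(c(1, 0.2, 0.3, 1), 2, byrow = TRUE), ss, g)

  base <- c(2, 1)
  sides <- lapply(1:6, function(i) detector_readings(ss, base))
  names(sides) <- c("A", "B", "C", "D", "E", "F")
  sides$D <- detector_readings(ss, 2 * base) # noiseless scaled side
  camp <- cube_campaign(sides)

  sp <- unfold_sides(camp, model)
  expect_named(sp, c("A", "B", "C", "D", "E", "F"))
  expect_equal(sp$A$values, sp$B$values)
  expect_rel_equal(sp$D$values, 2 * sp$E$values) # no clipping: exact scaling
  expect_equal(sp$E$meta$side, "E")

  bad <- unfolding_model(diag(2), sphere_set(c(0, 6), cd_covered = c(FALSE, FALSE)), g)
  expect_error(unfold_sides(camp, bad), "sphere sets")
})

test_that("mean_spectrum is the per-group arithmetic mean", {
  t1 <- table1_fixture()
  m <- mean_spectrum(t1$sides)
  # first published row: the six side values average to 9.84e3 (3 s.f.)
  expect_equal(signif(m$values[1], 3), 9.84e3)

  # six identical spectra reproduce the spectrum
  same <- mean_spectrum(rep(list(t1$mean), 6))
  expect_equal(same$values, t1$mean$values)

  # brute-force elementwise oracle on random spectra
  g <- build_output_grid()
  withr::with_seed(31, {
    sides <- lapply(1:6, function(i) spectrum(g, stats::rexp(25)))
  })
  got <- mean_spectrum(sides)
  oracle <- numeric(25)
  for (s in sides) oracle <- oracle + s$values / 6
  expect_rel_equal(got$values, oracle)

  # scaling commutes with averaging
  scaled <- mean_spectrum(lapply(sides, function(s) spectrum(g, 3 * s$values)))
  expect_rel_equal(scaled$values, 3 * got$values)
})

test_that("reported mean columns are audited against the recomputed mean", {
  t1 <- table1_fixture()
  flags <- check_reported_mean(t1$sides, t1$mean, tol = 0.01)
  g <- t1$grid$group_energies
  # rows verified to be true arithmetic means
  expect_false(flags[g == 1.03e-9])
  expect_false(flags[g == 1.87e-8])
  expect_false(flags[g == 1.87e-1])
  # rows known to be internally inconsistent in the published table
  expect_true(flags[g == 3.28e-7])
  expect_true(flags[g == 1.03e-6])
})

test_that("fluence-vs-diameter series are ordered with per-side peaks", {
  g <- build_training_grid()
  R <- build_response_matrix(sphere_set(), g)
  th <- spectrum_preset("thermal", g)
  camp <- simulate_campaign(rep(list(th), 6), R)

  fv <- fluence_vs_diameter(camp)
  expect_equal(nrow(fv), 54)
  expect_equal(sum(fv$side == "A"), 9)
  expect_equal(fv$diameter_in[fv$side == "A"], c(0, 2, 3, 4, 5, 6, 8, 10, 12))
  # thermal-dominated field: the bare cube (diameter 0) reads highest because
  # the cadmium-covered spheres absorb incident thermal neutrons
  peaks <- attr(fv, "peak_diameter_in")
  expect_true(all(peaks <= 2))

  zero <- cube_campaign(stats::setNames(lapply(1:6, function(i) {
    detector_readings(sphere_set(), rep(0, 9))
  }), c("A", "B", "C", "D", "E", "F")))
  fz <- fluence_vs_diameter(zero)
  expect_true(all(fz$reading == 0))
  expect_true(all(is.na(attr(fz, "peak_diameter_in"))))
})

test_that("find_peaks locates the published thermal and fast peaks", {
  t1 <- table1_fixture()
  pk <- find_peaks(t1$mean)
  expect_equal(pk$fast$energy, 1.87e-1)
  expect_equal(pk$fast$height, 2.19e6)
  # thermal maximum 6.66e5 appears at both 3.28e-8 and 5.78e-8; the tie
  # breaks to the lower energy group
  expect_equal(pk$thermal$height, 6.66e5)
  expect_equal(pk$thermal$energy, 3.28e-8)
  expect_lt(pk$thermal$energy, pk$fast$energy)

  # a single group inside the fast window is that window's peak
  g <- build_output_grid()
  one <- spectrum(g, as.numeric(g$group_energies == 5.78e-2))
  expect_equal(find_peaks(one)$fast$energy, 5.78e-2)

  expect_error(find_peaks(t1$mean, thermal_bound = 1e-12), "thermal_bound")
})

test_that("two-peak presets always order thermal below fast", {
  for (grid in list(build_output_grid(), build_training_grid())) {
    pk <- find_peaks(spectrum_preset("photoneutron", grid))
    expect_lt(pk$thermal$energy, pk$fast$energy)
  }
})

test_that("field-size trend recovers the least-squares line", {
  # the five published mean energies at field sides 0-40 cm
  tr <- field_size_trend(c(0, 10, 20, 30, 40), c(0.44, 0.48, 0.50, 0.51, 0.53))
  expect_equal(tr$slope, 0.0021, tolerance = 1e-9)
  expect_equal(tr$intercept, 0.450, tolerance = 1e-9)
  expect_gt(tr$correlation, 0.97)

  two <- field_size_trend(c(0, 10), c(0.4, 0.5))
  expect_equal(two$slope, 0.01, tolerance = 1e-12)
  expect_equal(two$intercept, 0.4, tolerance = 1e-12)

  flat <- field_size_trend(c(0, 10, 20), c(0.5, 0.5, 0.5))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$correlation, 0)

  # exact recovery on synthetic collinear points
  withr::with_seed(33, {
    x <- sort(stats::runif(6, 0, 40))
    a <- stats::runif(1, 0.3, 0.6)
    b <- stats::runif(1, 0, 0.01)
    tr2 <- field_size_trend(x, a + b * x)
    expect_equal(tr2$slope, b, tolerance = 1e-12)
    expect_equal(tr2$intercept, a, tolerance = 1e-12)
  })

  expect_error(field_size_trend(c(1, 1), c(0.4, 0.5)), "distinct")
})

test_that("dose equivalent weights fluence and reports the fast fraction", {
  g <- build_output_grid()
  pn <- spectrum_preset("photoneutron", g)

  flat <- dose_equivalent(pn, rep(1, 25))
  expect_rel_equal(flat$total, total_fluence(pn))
  e <- g$group_energies
  expect_rel_equal(flat$fraction_above, sum(pn$values[e >= 0.5]) / total_fluence(pn))

  delta <- spectrum(g, as.numeric(e == 1.03))
  h <- rep(0, 25)
  h[e == 1.03] <- 7
  de <- dose_equivalent(delta, h)
  expect_equal(de$total, 7)
  expect_equal(de$fraction_above, 1)

  # monotone-increasing coefficients vs a brute-force partial-sum oracle
  hmono <- seq_len(25)
  de2 <- dose_equivalent(pn, hmono, e_star = 0.5)
  num <- 0
  den <- 0
  for (i in 1:25) {
    den <- den + hmono[i] * pn$values[i]
    if (e[i] >= 0.5) num <- num + hmono[i] * pn$values[i]
  }
  expect_rel_equal(de2$total, den)
  expect_rel_equal(de2$fraction_above, num / den)
  expect_gte(de2$fraction_above, 0)
  expect_lte(de2$fraction_above, 1)

  expect_error(dose_equivalent(spectrum(g, rep(0, 25)), rep(1, 25)), "zero")
})
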