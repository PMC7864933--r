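test_that("component families discretize to unit-fluence spectra with the right shapes", {
  # thermal Maxwellian peaks at E = kT on a fine linear grid (constant bin width)
  gl <- energy_grid(seq(5e-9, 2e-7, length.out = 500))
  mx <- component_spectrum("maxwellian_thermal", list(kt = 2.53e-8), gl)
  expect_lt(abs(gl$group_energies[which.max(mx$values)] / 2.53e-8 - 1), 0.01)

  # every family normalizes to unit total fluence
  g <- build_training_grid()
  for (kind in c("maxwellian_thermal", "one_over_e", "evaporation_fast",
                 "watt", "lethargy_gaussian")) {
    s <- component_spectrum(kind, grid = g)
    expect_rel_equal(total_fluence(s), 1, tol = 1e-9)
    expect_true(all(s$values >= 0))
  }

  # Watt mean energy: numeric integration on a 2000-point grid against the
  # closed form 3a/2 + a^2 b / 4
  gw <- energy_grid(exp(seq(log(1e-4), log(100), length.out = 2000)))
  wt <- component_spectrum("watt", list(a = 1.025, b = 2.926), gw)
  expect_lt(abs(mean_energy(wt) / (3 * 1.025 / 2 + 1.025^2 * 2.926 / 4) - 1), 1e-4)

  # 1/E tail has no fluence outside its window
  oe <- component_spectrum("one_over_e", list(e_min = 1e-6, e_max = 1e-2), g)
  e <- g$group_energies
  expect_true(all(oe$values[e < 3e-7] == 0))
  expect_true(all(oe$values[e > 3e-2] == 0))

  expect_error(component_spectrum("nope", grid = g), "arg")
})

test_that("compose mixes unit-fluence components by weight", {
  g <- build_training_grid()
  one <- compose(list(list(kind = "watt", weight = 1)), g)
  expect_equal(one$values, component_spectrum("watt", grid = g)$values)

  with_zero <- compose(list(
    list(kind = "watt", weight = 2),
    list(kind = "maxwellian_thermal", weight = 0)
  ), g)
  expect_equal(with_zero$values, 2 * component_spectrum("watt", grid = g)$values)
  expect_rel_equal(total_fluence(with_zero), 2)

  expect_error(compose(list(list(kind = "watt", weight = 0)), g), "weight")
})

test_that("photoneutron preset shows the two-peak shape", {
  # on a uniform geometric grid: exactly two interior local maxima, the
  # thermal one below 1e-6 MeV and the fast one inside 0.05-1.0 MeV
  g60 <- build_training_grid()
  pn <- spectrum_preset("photoneutron", g60)
  v <- pn$values
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  expect_length(peaks, 2)
  expect_lt(g60$group_energies[peaks[1]], 1e-6)
  expect_gte(g60$group_energies[peaks[2]], 0.05)
  expect_lte(g60$group_energies[peaks[2]], 1.0)

  # on the irregular 25-group output grid the unequal lethargy widths add a
  # shallow ripple, so assert the regional two-peak structure instead:
  # a thermal peak, a fast peak, and a dip in between
  pn25 <- spectrum_preset("photoneutron", build_output_grid())
  pk <- find_peaks(pn25)
  expect_lt(pk$thermal$energy, 1e-6)
  expect_gte(pk$fast$energy, 0.05)
  mid <- min(pn25$values[pn25$grid$group_energies > 1e-6 &
                           pn25$grid$group_energies < 0.05])
  expect_lt(mid, 0.5 * pk$thermal$height)
  expect_lt(mid, 0.5 * pk$fast$height)
  expect_rel_equal(total_fluence(pn25), 1, tol = 1e-9)
})

test_that("compendium sampling is reproducible, normalized and spans decades", {
  g <- build_training_grid()
  a <- sample_compendium(5, g, seed = 7)
  b <- sample_compendium(5, g, seed = 7)
  expect_equal(lapply(a, `[[`, "values"), lapply(b, `[[`, "values"))

  lib <- sample_compendium(500, g, seed = 8)
  tots <- vapply(lib, total_fluence, numeric(1))
  expect_true(all(abs(tots - 1) < 1e-9))
  expect_true(all(vapply(lib, function(s) all(s$values >= 0), logical(1))))
  me <- vapply(lib, mean_energy, numeric(1))
  expect_gte(log10(max(me) / min(me)), 3)
})

test_that("Poisson track noise has the right first two moments", {
  g <- build_training_grid(20, 1e-8, 20)
  R <- build_response_matrix(sphere_set(), g)
  s <- spectrum_preset("photoneutron", g)
  clean <- fold(R, s)

  expect_equal(simulate_readings(R, s, noise_model("none"))$values, clean$values)
  n1 <- simulate_readings(R, s, noise_model("poisson_tracks", calibration = 10,
                                            background = 50, seed = 5))
  n2 <- simulate_readings(R, s, noise_model("poisson_tracks", calibration = 10,
                                            background = 50, seed = 5))
  expect_equal(n1$values, n2$values)

  # Monte-Carlo mean of the track counts vs calibration * fold + background,
  # and variance ~ mean (Poisson), over 1e4 replicates
  calib <- 10
  mu <- calib * clean$values + 50
  tracks <- vapply(1:10000, function(i) {
    simulate_readings(R, s, noise_model("poisson_tracks", calibration = calib,
                                        background = 50, seed = 10000 + i))$meta$tracks
  }, numeric(length(mu)))
  emp_mean <- rowMeans(tracks)
  se <- sqrt(mu / 10000)
  expect_true(all(abs(emp_mean - mu) < 3.5 * se))
  emp_var <- apply(tracks, 1, stats::var)
  expect_true(all(emp_var / mu > 0.9 & emp_var / mu < 1.1))
})

test_that("campaign simulation yields 54 readings with side-wise linearity", {
  g <- build_training_grid()
  R <- build_response_matrix(sphere_set(), g)
  s <- spectrum_preset("photoneutron", g)

  camp <- simulate_campaign(rep(list(s), 6), R)
  expect_equal(campaign_size(camp), 54L)
  for (lab in c("B", "C", "D", "E", "F")) {
    expect_equal(camp$sides[[lab]]$values, camp$sides$A$values)
  }

  s_up <- spectrum(g, s$values * 1.1)
  camp2 <- simulate_campaign(list(s, s, s, s_up, s, s), R)
  expect_true(all(camp2$sides$D$values >= camp2$sides$E$values))

  expect_error(simulate_campaign(rep(list(s), 5), R), "six")
})
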