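# Shared fixtures; the trained unfolder is expensive (full convergence to the
# least-squares optimum), so it is built once per session and cached.

.cache <- new.env(parent = emptyenv())

# Convergence-grade configuration: no early stop, step floor low enough to
# polish the ill-conditioned directions, all pairs used for training.
convergence_config <- function(seed = 1, epochs = 1e6) {
  train_config(epochs = epochs, tol = 0, delta_min = 1e-14,
               val_fraction = 0, seed = seed)
}

trained_fixture <- function() {
  if (is.null(.cache$model)) {
    ts <- training_set(500, seed = 1)
    .cache$ts <- ts
    .cache$model <- train_rprop(ts$targets, ts$readings, convergence_config(seed = 1))
  }
  list(ts = .cache$ts, model = .cache$model)
}

# small two-group toy problem where readings == spectrum (identity response)
toy_identity_pairs <- function(n = 40, seed = 3) {
  grid <- energy_grid(c(1, 3), label = "toy")
  ss <- sphere_set(c(0, 5), cd_covered = c(FALSE, FALSE))
  withr::with_seed(seed, {
    spectra <- lapply(seq_len(n), function(i) spectrum(grid, stats::runif(2, 0.1, 2)))
  })
  readings <- lapply(spectra, function(s) detector_readings(ss, s$values))
  list(grid = grid, ss = ss, spectra = spectra, readings = readings)
}

expect_rel_equal <- function(object, expected, tol = 1e-12) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)), tol)
}
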