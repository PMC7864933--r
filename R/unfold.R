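# Linear ANN unfolder: Rprop training, least-squares oracle, deployment ------

#' Training configuration for the Rprop unfolder
#'
#' Resilient-backpropagation step-size constants and bookkeeping. The
#' defaults are the standard published Rprop constants (eta+ = 1.2,
#' eta- = 0.5, Delta0 = 0.1, bounds 1e-6 / 50).
#'
#' @param epochs maximum full-batch epochs.
#' @param tol relative loss-improvement tolerance for early stopping.
#' @param eta_plus,eta_minus step multipliers on consistent / flipped
#'   gradient sign; `0 < eta_minus < 1 < eta_plus`.
#' @param delta0,delta_min,delta_max initial and clamping step sizes;
#'   `0 < delta_min <= delta0 <= delta_max`.
#' @param normalize scale inputs and outputs per feature to unit maximum
#'   during training (denormalized weights are stored).
#' @param val_fraction held-out fraction for the validation loss report.
#' @param seed seed for the train/validation shuffle.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 2000, tol = 1e-10, eta_plus = 1.2,
                         eta_minus = 0.5, delta0 = 0.1, delta_min = 1e-6,
                         delta_max = 50, normalize = TRUE, val_fraction = 0.2,
                         seed = 1) {
  stopifnot(epochs >= 1, tol >= 0, val_fraction >= 0, val_fraction < 1)
  if (!(0 < eta_minus && eta_minus < 1 && 1 < eta_plus)) {
    stop("need 0 < eta_minus < 1 < eta_plus", call. = FALSE)
  }
  if (!(0 < delta_min && delta_min <= delta0 && delta0 <= delta_max)) {
    stop("need 0 < delta_min <= delta0 <= delta_max", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), tol = tol, eta_plus = eta_plus,
                 eta_minus = eta_minus, delta0 = delta0, delta_min = delta_min,
                 delta_max = delta_max, normalize = isTRUE(normalize),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# Stack paired training lists into matrices Phi (m x N) and A (n x N);
# validates shared grids and sphere sets.
.stack_pairs <- function(spectra, readings) {
  if (!is.list(spectra) || !is.list(readings) ||
      length(spectra) != length(readings) || length(spectra) < 1L) {
    stop("'spectra' and 'readings' must be paired non-empty lists", call. = FALSE)
  }
  grid <- spectra[[1]]$grid
  ss <- readings[[1]]$sphere_set
  for (i in seq_along(spectra)) {
    stop_if_grid_mismatch(grid, spectra[[i]]$grid, sprintf("training spectrum %d", i))
    if (!same_sphere_set(ss, readings[[i]]$sphere_set)) {
      stop("training readings ", i, " use a different sphere set", call. = FALSE)
    }
  }
  m <- length(grid$group_energies)
  n <- length(ss$diameters)
  list(
    phi = matrix(vapply(spectra, function(s) s$values, numeric(m)), nrow = m),
    a = matrix(vapply(readings, function(r) r$values, numeric(n)), nrow = n),
    grid = grid, ss = ss
  )
}

# mean squared residual sum ||W a_j - phi_j||^2 over pairs, via the
# precomputed second moments: L = sphi - 2 sum(W * B) + sum((W C) * W)
.quad_loss <- function(W, C, B, sphi) {
  max(0, sphi - 2 * sum(W * B) + sum((W %*% C) * W))
}

#' Train the linear unfolder by resilient backpropagation
#'
#' Fits the synaptic-weight matrix W of a linear, bias-free, hidden-layer-free
#' network mapping sphere readings to group fluences, by minimizing the mean
#' squared error of `W %*% a` against the known spectra over the training set.
#' Full-batch Rprop adapts one step size per weight from the gradient sign
#' history (grow by `eta_plus` on a consistent sign, shrink by `eta_minus` and
#' skip the step on a sign flip, clamp to `[delta_min, delta_max]`). An
#' epoch-level safeguard rejects any epoch that would increase the training
#' loss (all step sizes shrink instead), so the reported loss trajectory is
#' non-increasing. Deterministic given the configuration seed and inputs.
#'
#' @param spectra list of training [spectrum] objects (shared grid).
#' @param readings paired list of [detector_readings()] (shared sphere set).
#' @param cfg a [train_config()].
#' @return An `unfolding_model`: fields `weights` (m_groups x n_configs),
#'   `input_set`, `output_grid` and `train_meta` (seed, epochs run, final and
#'   validation loss, loss history, normalization constants).
#' @seealso [ls_oracle()] for the closed-form minimizer, [unfold()].
#' @export
train_rprop <- function(spectra, readings, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  st <- .stack_pairs(spectra, readings)
  N <- ncol(st$a)
  m <- nrow(st$phi)
  n <- nrow(st$a)

  idx <- withr::with_seed(cfg$seed, sample.int(N))
  n_val <- floor(cfg$val_fraction * N)
  val <- if (n_val >= 1 && N - n_val >= n) idx[seq_len(n_val)] else integer(0)
  tr <- setdiff(idx, val)

  a_tr <- st$a[, tr, drop = FALSE]
  phi_tr <- st$phi[, tr, drop = FALSE]
  if (cfg$normalize) {
    amax <- apply(abs(a_tr), 1, max)
    pmax_ <- apply(abs(phi_tr), 1, max)
  } else {
    amax <- rep(1, n)
    pmax_ <- rep(1, m)
  }
  amax[amax == 0] <- 1
  pmax_[pmax_ == 0] <- 1
  an <- a_tr / amax
  pn <- phi_tr / pmax_

  ntr <- length(tr)
  C <- an %*% t(an) / ntr
  B <- pn %*% t(an) / ntr
  sphi <- sum(pn^2) / ntr

  W <- matrix(0, m, n)
  Delta <- matrix(cfg$delta0, m, n)
  g_prev <- matrix(0, m, n)
  loss <- .quad_loss(W, C, B, sphi)
  history <- numeric(cfg$epochs)
  epochs_run <- 0L
  for (ep in seq_len(cfg$epochs)) {
    g <- 2 * (W %*% C - B)
    if (any(!is.finite(g))) stop("training failure: non-finite gradient", call. = FALSE)
    sgn <- sign(g)
    prod_ <- sgn * sign(g_prev)
    Delta[prod_ > 0] <- pmin(Delta[prod_ > 0] * cfg$eta_plus, cfg$delta_max)
    Delta[prod_ < 0] <- pmax(Delta[prod_ < 0] * cfg$eta_minus, cfg$delta_min)
    step_sgn <- sgn
    step_sgn[prod_ < 0] <- 0 # skip the step right after a sign flip
    W_new <- W - step_sgn * Delta
    loss_new <- .quad_loss(W_new, C, B, sphi)
    if (!is.finite(loss_new)) stop("training failure: non-finite loss", call. = FALSE)
    if (loss_new > loss * (1 + 1e-12)) {
      # reject the epoch: shrink everything and forget the sign history
      Delta <- pmax(Delta * cfg$eta_minus, cfg$delta_min)
      g_prev <- matrix(0, m, n)
      history[ep] <- loss
    } else {
      g_prev <- g
      g_prev[prod_ < 0] <- 0
      W <- W_new
      improved <- loss - loss_new
      history[ep] <- loss_new
      converged <- cfg$tol > 0 &&
        improved <= cfg$tol * max(loss_new, .Machine$double.xmin)
      loss <- loss_new
      if (converged) {
        epochs_run <- ep
        break
      }
    }
    epochs_run <- ep
  }
  history <- history[seq_len(epochs_run)]

  W_raw <- W * pmax_ # row scaling
  W_raw <- sweep(W_raw, 2, amax, "/")

  val_loss <- if (length(val) > 0) {
    res <- W_raw %*% st$a[, val, drop = FALSE] - st$phi[, val, drop = FALSE]
    sum(res^2) / length(val)
  } else NA_real_

  unfolding_model(
    weights = W_raw, input_set = st$ss, output_grid = st$grid,
    train_meta = list(seed = cfg$seed, epochs = epochs_run, final_loss = loss,
                      val_loss = val_loss, loss_history = history,
                      n_train = ntr, n_val = length(val),
                      amax = amax, phimax = pmax_)
  )
}

#' Assemble an unfolding model from a weight matrix
#'
#' @param weights finite matrix, `n_groups x n_configurations`.
#' @param input_set the [sphere_set()] the readings come from.
#' @param output_grid the [energy_grid] of the unfolded spectra.
#' @param train_meta free-form training provenance.
#' @return An object of class `unfolding_model`.
#' @export
unfolding_model <- function(weights, input_set, output_grid, train_meta = list()) {
  stopifnot(inherits(input_set, "sphere_set"), inherits(output_grid, "energy_grid"))
  weights <- as.matrix(weights)
  if (nrow(weights) != length(output_grid$group_energies) ||
      ncol(weights) != length(input_set$diameters)) {
    stop("weights must be n_groups x n_configurations", call. = FALSE)
  }
  if (any(!is.finite(weights))) stop("weights must be finite", call. = FALSE)
  structure(list(weights = weights, input_set = input_set,
                 output_grid = output_grid, train_meta = train_meta),
            class = "unfolding_model")
}

#' @export
print.unfolding_model <- function(x, ...) {
  cat(sprintf("<unfolding_model> %d groups x %d configurations", nrow(x$weights),
              ncol(x$weights)))
  if (!is.null(x$train_meta$final_loss)) {
    cat(sprintf(", final training loss %.3e", x$train_meta$final_loss))
  }
  cat("\n")
  invisible(x)
}

#' Closed-form (ridge) least-squares weights
#'
#' The exact minimizer of the (optionally ridge-penalized) squared training
#' loss of the linear unfolder, `W = Phi A' (A A' + ridge I)^-1` with training
#' pairs as columns of `Phi` and `A`. Serves as the independent optimum the
#' Rprop-trained network is checked against.
#'
#' @param spectra,readings paired training lists as in [train_rprop()].
#' @param ridge nonnegative ridge penalty.
#' @return Plain weight matrix, `n_groups x n_configurations`.
#' @export
ls_oracle <- function(spectra, readings, ridge = 0) {
  assert_scalar_number(ridge, "ridge", nonneg = TRUE)
  st <- .stack_pairs(spectra, readings)
  G <- st$a %*% t(st$a) + diag(ridge, nrow(st$a))
  W <- tryCatch(
    t(solve(G, st$a %*% t(st$phi))),
    error = function(e) {
      stop("normal equations are numerically singular; use ridge > 0",
           call. = FALSE)
    }
  )
  W
}

#' Unfold detector readings into a spectrum
#'
#' Applies the trained synaptic weights, `phi_hat = W %*% a`, and clips
#' negative group fluences to zero (the linear network cannot enforce
#' nonnegativity); the indices of clipped groups are recorded in
#' `meta$clipped_groups`.
#'
#' @param model an `unfolding_model`.
#' @param a [detector_readings()] on the model's sphere set.
#' @return A [spectrum] on the model's output grid.
#' @export
unfold <- function(model, a) {
  stopifnot(inherits(model, "unfolding_model"), inherits(a, "detector_readings"))
  if (!same_sphere_set(model$input_set, a$sphere_set)) {
    stop("readings use a different sphere set than the model", call. = FALSE)
  }
  raw <- as.vector(model$weights %*% a$values)
  clipped <- which(raw < 0)
  spectrum(model$output_grid, pmax(raw, 0),
           meta = list(clipped_groups = clipped))
}

#' Monte-Carlo uncertainty of an unfolded spectrum
#'
#' Perturbs the readings with independent Gaussian noise of their stated
#' standard deviations (truncated at zero), unfolds each replicate, and
#' reports the per-group mean and standard deviation. Reproducible given the
#' seed.
#'
#' @param model an `unfolding_model`.
#' @param a [detector_readings()] with `sd` present.
#' @param n_mc number of replicates (>= 2).
#' @param seed integer seed.
#' @return A [spectrum] whose `values` are the replicate means and `sd` the
#'   replicate standard deviations.
#' @export
unfold_uncertainty <- function(model, a, n_mc = 1000, seed = 1) {
  stopifnot(inherits(model, "unfolding_model"), inherits(a, "detector_readings"))
  if (is.null(a$sd)) {
    stop("readings carry no 'sd'; uncertainty propagation needs one", call. = FALSE)
  }
  if (!is.numeric(n_mc) || n_mc < 2) stop("'n_mc' must be >= 2", call. = FALSE)
  n_mc <- as.integer(n_mc)
  n <- length(a$values)
  sims <- withr::with_seed(as.integer(seed), {
    pert <- matrix(stats::rnorm(n * n_mc, mean = a$values, sd = a$sd), n, n_mc)
    pmax(pert, 0)
  })
  phis <- pmax(model$weights %*% sims, 0)
  mu <- rowMeans(phis)
  sdv <- sqrt(rowMeans((phis - mu)^2) * n_mc / (n_mc - 1))
  spectrum(model$output_grid, mu, sd = sdv,
           meta = list(n_mc = n_mc, seed = as.integer(seed)))
}

#' Build a synthetic training set for the unfolder
#'
#' End-to-end generator of training material: samples a compendium-like
#' library on the (fine) training grid, folds every spectrum through the
#' parametric response matrix on that grid to obtain the readings, and rebins
#' the spectra onto the output grid as the network's targets. With
#' `noisy = TRUE` the readings are Poisson-perturbed instead of exact folds.
#'
#' @param n number of training pairs.
#' @param seed integer seed (drives compendium sampling and, when `noisy`,
#'   the Poisson draws).
#' @param ss a [sphere_set()].
#' @param params a [response_params()] list.
#' @param grid_train fine grid the library lives on.
#' @param grid_out grid of the unfolded spectra.
#' @param noisy add Poisson track noise to the training readings.
#' @param noise a [noise_model()] used when `noisy = TRUE`.
#' @return List with `targets` (spectra on `grid_out`), `readings`,
#'   `spectra` (the library on `grid_train`) and `response` (the response
#'   matrix on `grid_train`).
#' @export
training_set <- function(n = 500, seed = 1, ss = sphere_set(),
                         params = response_params(),
                         grid_train = build_training_grid(),
                         grid_out = build_output_grid(),
                         noisy = FALSE,
                         noise = noise_model("poisson_tracks", calibration = 1e6,
                                             background = 50, seed = seed)) {
  lib <- sample_compendium(n, grid_train, seed = seed)
  R <- build_response_matrix(ss, grid_train, params)
  readings <- if (noisy) {
    lapply(seq_along(lib), function(i) {
      ni <- noise
      ni$seed <- noise$seed + i
      simulate_readings(R, lib[[i]], ni)
    })
  } else {
    lapply(lib, function(s) fold(R, s))
  }
  targets <- lapply(lib, rebin, target = grid_out)
  list(targets = targets, readings = readings, spectra = lib, response = R)
}

# Model JSON ------------------------------------------------------------------

#' Serialize / restore an unfolding model as JSON
#'
#' Numbers are written with 17 significant digits so that a write-read round
#' trip reproduces the weights bit for bit.
#'
#' @param model an `unfolding_model`.
#' @param path file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns the `unfolding_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "unfolding_model"))
  payload <- list(
    weights = model$weights,
    diameters = model$input_set$diameters,
    cd_covered = model$input_set$cd_covered,
    group_energies = model$output_grid$group_energies,
    grid_label = model$output_grid$label,
    train_meta = model$train_meta
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  unfolding_model(
    weights = matrix(as.numeric(p$weights), nrow = length(p$group_energies),
                     byrow = FALSE),
    input_set = sphere_set(as.numeric(p$diameters), as.logical(p$cd_covered)),
    output_grid = energy_grid(as.numeric(p$group_energies),
                              label = p$grid_label %||% ""),
    train_meta = p$train_meta %||% list()
  )
}
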