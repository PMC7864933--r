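# Synthetic spectra, compendium sampling, noisy measurement simulation -------

COMPONENT_KINDS <- c("maxwellian_thermal", "one_over_e", "evaporation_fast",
                     "watt", "lethargy_gaussian")

# (1 + x) exp(-x): survival-type helper of the E*exp(-E/T) family,
# integral of t*exp(-t) from x to infinity (per T^2).
.gx <- function(x) (1 + x) * exp(-x)

# Watt fission density exp(-E/a)*sinh(sqrt(b*E)), evaluated overflow-safe.
.watt_density <- function(E, a, b) {
  s <- sqrt(b * E)
  0.5 * (exp(s - E / a) - exp(-s - E / a))
}

# integral of density over [lo, hi] by trapezoid in log energy
.numeric_bin_integral <- function(dens, lo, hi) {
  k <- max(16L, ceiling(50 * (log(hi) - log(lo))))
  lx <- seq(log(lo), log(hi), length.out = k)
  x <- exp(lx)
  y <- dens(x) * x # dE = E dlnE
  sum((y[-1] + y[-k]) / 2) * (lx[2] - lx[1])
}

#' Single-family synthetic spectrum
#'
#' Discretizes one parametric spectral family onto a grid as true group
#' fluences (the density integrated over each bin, bin edges from
#' [grid_edges()]), normalized to unit total fluence. Families:
#'
#' * `maxwellian_thermal`: density `E * exp(-E/kT)`; `params$kt`
#'   (default 2.53e-8 MeV).
#' * `one_over_e`: density `1/E` on the window `params$e_min`..`params$e_max`
#'   (defaults 1e-8 and 1 MeV) -- the epithermal tail, flat per unit lethargy.
#' * `evaporation_fast`: density `E * exp(-E/T_f)`; `params$t_f`
#'   (default 0.4 MeV).
#' * `watt`: fission density `exp(-E/a) * sinh(sqrt(b*E))`; `params$a`,
#'   `params$b` (defaults 1.025 MeV and 2.926 MeV^-1, a common choice for a
#'   Cf-252 source).
#' * `lethargy_gaussian`: fluence Gaussian in ln(E); `params$center` (MeV,
#'   default 1) and `params$width` (in ln E, default 1).
#'
#' @param kind one of the family names above.
#' @param params named list of family parameters (defaults above).
#' @param grid an [energy_grid].
#' @return A unit-fluence [spectrum].
#' @export
#' @examples
#' g <- build_training_grid()
#' total_fluence(component_spectrum("watt", grid = g))  # 1
component_spectrum <- function(kind, params = list(), grid) {
  kind <- match.arg(kind, COMPONENT_KINDS)
  stopifnot(inherits(grid, "energy_grid"))
  ed <- grid_edges(grid)
  lo <- ed[-length(ed)]
  hi <- ed[-1]
  vals <- switch(kind,
    maxwellian_thermal = {
      kt <- assert_scalar_number(params$kt %||% 2.53e-8, "kt", positive = TRUE)
      kt^2 * (.gx(lo / kt) - .gx(hi / kt))
    },
    evaporation_fast = {
      tf <- assert_scalar_number(params$t_f %||% 0.4, "t_f", positive = TRUE)
      tf^2 * (.gx(lo / tf) - .gx(hi / tf))
    },
    one_over_e = {
      e_min <- assert_scalar_number(params$e_min %||% 1e-8, "e_min", positive = TRUE)
      e_max <- assert_scalar_number(params$e_max %||% 1, "e_max", positive = TRUE)
      if (e_min >= e_max) stop("one_over_e: 'e_min' must be < 'e_max'", call. = FALSE)
      pmax(0, log(pmin(hi, e_max)) - log(pmax(lo, e_min))) *
        (hi > e_min & lo < e_max)
    },
    watt = {
      a <- assert_scalar_number(params$a %||% 1.025, "a", positive = TRUE)
      b <- assert_scalar_number(params$b %||% 2.926, "b", positive = TRUE)
      vapply(seq_along(lo), function(i) {
        .numeric_bin_integral(function(E) .watt_density(E, a, b), lo[i], hi[i])
      }, numeric(1))
    },
    lethargy_gaussian = {
      center <- assert_scalar_number(params$center %||% 1, "center", positive = TRUE)
      width <- assert_scalar_number(params$width %||% 1, "width", positive = TRUE)
      stats::pnorm(log(hi / center) / width) - stats::pnorm(log(lo / center) / width)
    }
  )
  vals <- pmax(vals, 0)
  tot <- sum(vals)
  if (!is.finite(tot) || tot <= 0) {
    stop("component '", kind, "' has no support on this grid", call. = FALSE)
  }
  spectrum(grid, vals / tot, meta = list(kind = kind, params = params))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted mixture of spectral components
#'
#' Each component is discretized to unit fluence by [component_spectrum()] and
#' the mixture is the weighted sum, so the total fluence equals the sum of the
#' weights.
#'
#' @param components list of `list(kind =, params =, weight =)` entries;
#'   weights nonnegative with at least one positive.
#' @param grid an [energy_grid].
#' @return A [spectrum] with total fluence `sum(weights)`.
#' @export
compose <- function(components, grid) {
  stopifnot(is.list(components), length(components) >= 1L,
            inherits(grid, "energy_grid"))
  w <- vapply(components, function(cc) {
    assert_scalar_number(cc$weight %||% 1, "weight", nonneg = TRUE)
  }, numeric(1))
  if (sum(w) <= 0) stop("at least one component weight must be > 0", call. = FALSE)
  vals <- numeric(length(grid$group_energies))
  for (i in seq_along(components)) {
    if (w[i] == 0) next
    cc <- components[[i]]
    vals <- vals + w[i] *
      component_spectrum(cc$kind, cc$params %||% list(), grid)$values
  }
  spectrum(grid, vals, meta = list(components = components))
}

#' Named spectrum presets
#'
#' * `"photoneutron"`: the two-peak photoneutron shape of a high-energy
#'   medical linac field -- thermal Maxwellian (kT = 2.53e-8 MeV, weight
#'   0.15), epithermal 1/E tail (weight 0.25), evaporation fast peak
#'   (T_f = 0.4 MeV, weight 0.60); unit total fluence.
#' * `"cf252"`: Watt fission spectrum, a = 1.025 MeV, b = 2.926 MeV^-1.
#' * `"thermal"`: pure thermal Maxwellian, kT = 2.53e-8 MeV.
#'
#' @param name preset name.
#' @param grid an [energy_grid].
#' @return A unit-fluence [spectrum].
#' @export
spectrum_preset <- function(name = c("photoneutron", "cf252", "thermal"),
                            grid = build_output_grid()) {
  name <- match.arg(name)
  comps <- switch(name,
    photoneutron = list(
      list(kind = "maxwellian_thermal", params = list(kt = 2.53e-8), weight = 0.15),
      list(kind = "one_over_e", params = list(e_min = 1e-8, e_max = 1), weight = 0.25),
      list(kind = "evaporation_fast", params = list(t_f = 0.4), weight = 0.60)),
    cf252 = list(
      list(kind = "watt", params = list(a = 1.025, b = 2.926), weight = 1)),
    thermal = list(
      list(kind = "maxwellian_thermal", params = list(kt = 2.53e-8), weight = 1))
  )
  s <- compose(comps, grid)
  s$meta$preset <- name
  s
}

#' Sample a compendium-like library of spectra
#'
#' Draws `n` unit-fluence spectra from randomized mixtures of the parametric
#' families, emulating the spectral variety of a reference compendium spanning
#' thermal to fast energies: 2-4 distinct families per spectrum, temperatures
#' and windows drawn log-uniformly over physically plausible ranges, mixture
#' weights from a flat simplex. A pure function of `(n, grid, seed)`.
#'
#' @param n number of spectra (>= 1).
#' @param grid an [energy_grid].
#' @param seed integer seed.
#' @return List of `n` unit-fluence [spectrum] objects.
#' @export
sample_compendium <- function(n, grid = build_training_grid(), seed = 1) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      k <- sample(2:4, 1)
      kinds <- sample(COMPONENT_KINDS, k)
      comps <- lapply(kinds, function(kind) {
        params <- switch(kind,
          # moderated thermal neutrons sit near room temperature; only the
          # moderator temperature (~235-350 K) moves the Maxwellian
          maxwellian_thermal = list(kt = 2.53e-8 * stats::runif(1, 0.8, 1.2)),
          one_over_e = {
            # epithermal tail: starts a few kT above thermal, ends where the
            # fast peak takes over
            list(e_min = 10^stats::runif(1, log10(2e-8), -7),
                 e_max = 10^stats::runif(1, -2, 0))
          },
          # evaporation / nuclear temperatures of (gamma,n) and fission sources
          evaporation_fast = list(t_f = stats::runif(1, 0.2, 1.5)),
          watt = list(a = stats::runif(1, 0.9, 1.2), b = stats::runif(1, 2.5, 3.5)),
          # broad moderated bumps; widths below ~1 in ln E are narrower than a
          # moderating-sphere set can resolve and are not workplace-like
          lethargy_gaussian = list(center = 10^stats::runif(1, -7, 0.8),
                                   width = stats::runif(1, 1, 2))
        )
        list(kind = kind, params = params, weight = stats::rexp(1))
      })
      s <- compose(comps, grid)
      s$values <- s$values / sum(s$values)
      s$meta$compendium_index <- i
      s
    })
  })
}

#' Track-counting noise model
#'
#' `mode = "none"` reproduces the noiseless forward fold. With
#' `mode = "poisson_tracks"` the expected alpha-track count of a detector is
#' `calibration * reading + background`; the observed count is Poisson, and
#' the reading is recovered as `(tracks - background) / calibration` (floored
#' at zero) with standard deviation `sqrt(tracks) / calibration` -- physical
#' counting statistics of etched-track densities.
#'
#' @param mode `"none"` or `"poisson_tracks"`.
#' @param calibration tracks per unit fluence (> 0 for Poisson mode).
#' @param background mean background track density (tracks cm^-2).
#' @param seed integer seed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(mode = c("none", "poisson_tracks"), calibration = 1,
                        background = 50, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "poisson_tracks") {
    assert_scalar_number(calibration, "calibration", positive = TRUE)
    assert_scalar_number(background, "background", nonneg = TRUE)
  }
  structure(list(mode = mode, calibration = calibration,
                 background = background, seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate detector readings for a spectrum
#'
#' @param R a `response_matrix`.
#' @param s a [spectrum] on the same grid.
#' @param noise a [noise_model()].
#' @return [detector_readings()]; with Poisson noise, `sd` carries the
#'   counting uncertainty and `meta$tracks` the simulated track counts.
#' @export
simulate_readings <- function(R, s, noise = noise_model("none")) {
  stopifnot(inherits(noise, "noise_model"))
  clean <- fold(R, s)
  if (noise$mode == "none") {
    clean$sd <- rep(0, length(clean$values))
    return(clean)
  }
  mu_tracks <- noise$calibration * clean$values + noise$background
  tracks <- withr::with_seed(noise$seed, stats::rpois(length(mu_tracks), mu_tracks))
  detector_readings(
    R$sphere_set,
    pmax(0, tracks - noise$background) / noise$calibration,
    sd = sqrt(tracks) / noise$calibration,
    meta = list(tracks = tracks, noise = noise)
  )
}

#' Simulate a six-side cube campaign
#'
#' One spectrum per cube side A-F, folded through the same response matrix;
#' with the default nine-configuration sphere set this yields the campaign's
#' 54 scalar readings. Under Poisson noise each side uses `noise$seed + side`
#' so sides are independent but the campaign is reproducible.
#'
#' @param side_spectra list of exactly six [spectrum] objects (sides A-F, in
#'   order), all on the grid of `R`.
#' @param R a `response_matrix`.
#' @param noise a [noise_model()].
#' @param location free-text location label.
#' @param exposure numeric `c(Gy =, MU =)` exposure metadata.
#' @return A [cube_campaign()].
#' @export
simulate_campaign <- function(side_spectra, R, noise = noise_model("none"),
                              location = "", exposure = c(Gy = 5, MU = 500)) {
  if (!is.list(side_spectra) || length(side_spectra) != 6L) {
    stop("exactly six side spectra (A-F) are required", call. = FALSE)
  }
  sides <- lapply(seq_len(6L), function(i) {
    ni <- noise
    if (noise$mode != "none") ni$seed <- noise$seed + i
    simulate_readings(R, side_spectra[[i]], ni)
  })
  names(sides) <- SIDE_LABELS
  cube_campaign(sides, location = location, exposure = exposure)
}
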