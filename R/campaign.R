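# Six-side cube campaigns and the directional analyses -----------------------

SIDE_LABELS <- c("A", "B", "C", "D", "E", "F")

#' Six-side cube campaign
#'
#' Readings of the six cube-side detectors (A-F) across the shared moderator
#' configurations; the default nine-configuration sphere set gives the
#' campaign's 54 scalar readings. Exposure metadata records the delivered
#' X-ray dose; the monitor-unit convention is 1 MU = 1 cGy at the depth of
#' maximum dose, so a 5 Gy exposure is 500 MU.
#'
#' @param sides named list of six [detector_readings()], names `A`..`F`, all
#'   on one sphere set.
#' @param location free-text measurement-location label.
#' @param exposure numeric `c(Gy =, MU =)`.
#' @return An object of class `cube_campaign`.
#' @export
cube_campaign <- function(sides, location = "", exposure = c(Gy = 5, MU = 500)) {
  if (!is.list(sides) || length(sides) != 6L) {
    stop("a cube campaign has exactly six sides (A-F)", call. = FALSE)
  }
  if (is.null(names(sides)) || !identical(sort(names(sides)), SIDE_LABELS)) {
    missing <- setdiff(SIDE_LABELS, names(sides))
    stop(if (length(missing)) paste("missing side", missing[1])
         else "side names must be A..F", call. = FALSE)
  }
  sides <- sides[SIDE_LABELS]
  ss <- sides[[1]]$sphere_set
  for (lab in SIDE_LABELS) {
    if (!inherits(sides[[lab]], "detector_readings")) {
      stop("side ", lab, " is not a detector_readings object", call. = FALSE)
    }
    if (!same_sphere_set(ss, sides[[lab]]$sphere_set)) {
      stop("side ", lab, " uses a different sphere set", call. = FALSE)
    }
  }
  structure(list(sides = sides, sphere_set = ss, location = location,
                 exposure = exposure),
            class = "cube_campaign")
}

#' @export
print.cube_campaign <- function(x, ...) {
  cat(sprintf("<cube_campaign>%s %d sides x %d configurations = %d readings\n",
              if (nzchar(x$location)) paste0(" '", x$location, "'") else "",
              length(x$sides), length(x$sphere_set$diameters),
              length(x$sides) * length(x$sphere_set$diameters)))
  invisible(x)
}

#' Number of scalar readings in a campaign
#'
#' @param c a [cube_campaign()].
#' @return Count of side x configuration readings (54 for the default setup).
#' @export
campaign_size <- function(c) {
  stopifnot(inherits(c, "cube_campaign"))
  length(c$sides) * length(c$sphere_set$diameters)
}

#' Convert a track density to a fluence
#'
#' Background-corrected conversion of an etched-track density to a thermal
#' neutron fluence: `(density - background) / calibration`, floored at zero,
#' with the density and background uncertainties combined in quadrature.
#'
#' @param density mean track density (tracks cm^-2).
#' @param density_sd its standard deviation.
#' @param background mean background track density.
#' @param background_sd its standard deviation.
#' @param calibration tracks per unit fluence (> 0).
#' @return `c(fluence =, sd =)` in n cm^-2.
#' @export
#' @examples
#' track_to_fluence(1000, 30, 100, 40, 0.9)
track_to_fluence <- function(density, density_sd = 0, background = 0,
                             background_sd = 0, calibration) {
  assert_scalar_number(density, "density", nonneg = TRUE)
  assert_scalar_number(density_sd, "density_sd", nonneg = TRUE)
  assert_scalar_number(background, "background", nonneg = TRUE)
  assert_scalar_number(background_sd, "background_sd", nonneg = TRUE)
  assert_scalar_number(calibration, "calibration", positive = TRUE)
  c(fluence = max(0, density - background) / calibration,
    sd = sqrt(density_sd^2 + background_sd^2) / calibration)
}

#' Unfold all six sides of a campaign
#'
#' @param c a [cube_campaign()].
#' @param model an `unfolding_model` on the campaign's sphere set.
#' @return Named list (`A`..`F`) of unfolded [spectrum] objects.
#' @export
unfold_sides <- function(c, model) {
  stopifnot(inherits(c, "cube_campaign"))
  if (!same_sphere_set(c$sphere_set, model$input_set)) {
    stop("campaign and model use different sphere sets", call. = FALSE)
  }
  out <- lapply(c$sides, function(a) unfold(model, a))
  for (lab in names(out)) out[[lab]]$meta$side <- lab
  out
}

#' Per-group arithmetic mean of side spectra
#'
#' @param sides list of [spectrum] objects on one grid (typically the six
#'   sides A-F).
#' @return The mean [spectrum].
#' @export
mean_spectrum <- function(sides) {
  if (!is.list(sides) || length(sides) < 1L) {
    stop("'sides' must be a non-empty list of spectra", call. = FALSE)
  }
  grid <- sides[[1]]$grid
  for (i in seq_along(sides)) {
    stop_if_grid_mismatch(grid, sides[[i]]$grid, sprintf("side spectrum %d", i))
  }
  vals <- rowMeans(vapply(sides, function(s) s$values,
                          numeric(length(grid$group_energies))))
  spectrum(grid, vals, meta = list(n_sides = length(sides)))
}

#' Flag rows of a reported mean column that disagree with the side values
#'
#' Recomputes the per-group arithmetic mean of the side spectra and flags
#' groups where a reported "mean" column deviates by more than `tol`
#' (relative). Published tables are occasionally internally inconsistent;
#' this makes such rows explicit rather than silently trusting them.
#'
#' @param sides list of side [spectrum] objects.
#' @param reported the reported mean [spectrum].
#' @param tol relative tolerance (default 1%).
#' @return Logical vector, `TRUE` where the reported value deviates; the
#'   relative deviations are attached as attribute `rel_dev`.
#' @export
check_reported_mean <- function(sides, reported, tol = 0.01) {
  m <- mean_spectrum(sides)
  stop_if_grid_mismatch(m$grid, reported$grid, "reported mean")
  rel <- abs(reported$values - m$values) / pmax(m$values, .Machine$double.xmin)
  structure(rel > tol, rel_dev = rel)
}

#' Fluence-versus-diameter series of a campaign
#'
#' The raw readings of every side ordered by moderator diameter (bare cube
#' first), the direct diagnostic plot of a multi-sphere campaign; also
#' reports, per side, the diameter at which the reading peaks.
#'
#' @param c a [cube_campaign()].
#' @return `data.frame` with columns `side`, `diameter_in`, `reading` (and
#'   `sd` when available); the per-side peak diameters are attached as
#'   attribute `peak_diameter_in` (named numeric).
#' @export
fluence_vs_diameter <- function(c) {
  stopifnot(inherits(c, "cube_campaign"))
  d <- c$sphere_set$diameters
  out <- do.call(rbind, lapply(names(c$sides), function(lab) {
    r <- c$sides[[lab]]
    df <- data.frame(side = lab, diameter_in = d, reading = r$values)
    if (!is.null(r$sd)) df$sd <- r$sd
    df
  }))
  peaks <- vapply(c$sides, function(r) {
    if (all(r$values == 0)) NA_real_ else d[which.max(r$values)]
  }, numeric(1))
  attr(out, "peak_diameter_in") <- peaks
  out
}

#' Thermal and fast peak summary of a spectrum
#'
#' The thermal peak is the maximum group fluence over groups with energy at
#' most `thermal_bound`; the fast peak the maximum over groups with energy at
#' least `fast_lo`. Ties break toward the lower-energy group. The
#' fluence-weighted mean energy is attached.
#'
#' @param s a [spectrum] (ascending grid).
#' @param thermal_bound upper edge of the thermal/epithermal region (MeV).
#' @param fast_lo lower edge of the fast window (MeV).
#' @return An object of class `peak_summary`: lists `thermal` and `fast`,
#'   each `(energy, height)`, plus `mean_energy`.
#' @export
find_peaks <- function(s, thermal_bound = 1e-6, fast_lo = 5e-2) {
  stopifnot(inherits(s, "spectrum"))
  e <- s$grid$group_energies
  th <- which(e <= thermal_bound)
  fa <- which(e >= fast_lo)
  if (length(th) == 0L) stop("no groups at or below 'thermal_bound'", call. = FALSE)
  if (length(fa) == 0L) stop("no groups at or above 'fast_lo'", call. = FALSE)
  it <- th[which.max(s$values[th])] # which.max: first maximum = lower energy
  if_ <- fa[which.max(s$values[fa])]
  structure(list(
    thermal = list(energy = e[it], height = s$values[it]),
    fast = list(energy = e[if_], height = s$values[if_]),
    mean_energy = mean_energy(s)
  ), class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("thermal peak %s at %s MeV | fast peak %s at %s MeV | mean %s MeV\n",
              fmt_e(x$thermal$height), fmt_e(x$thermal$energy),
              fmt_e(x$fast$height), fmt_e(x$fast$energy), fmt_e(x$mean_energy)))
  invisible(x)
}

#' Linear trend of mean energy with field size
#'
#' Ordinary least-squares line (and Pearson correlation) through mean
#' photoneutron energy versus square-field side length, the standard check
#' that the spectrum hardens linearly as the collimator opens.
#'
#' @param field_cm field side lengths (cm), at least two distinct.
#' @param mean_energy_mev mean energies (MeV), same length.
#' @return List with `slope` (MeV/cm), `intercept` (MeV) and `correlation`.
#' @export
#' @examples
#' field_size_trend(c(0, 10, 20, 30, 40), c(0.44, 0.48, 0.50, 0.51, 0.53))
field_size_trend <- function(field_cm, mean_energy_mev) {
  x <- as.numeric(field_cm)
  y <- as.numeric(mean_energy_mev)
  if (length(x) != length(y) || length(unique(x)) < 2L) {
    stop("need >= 2 distinct field sizes with matching mean energies", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = if (stats::sd(y) > 0) stats::cor(x, y) else 0)
}

#' Dose equivalent of a spectrum
#'
#' Folds grid-aligned fluence-to-dose-equivalent coefficients with the group
#' fluences: `H = sum(h_g * phi_g)`, and the fraction of H contributed by
#' groups at or above the threshold energy (default 0.5 MeV, separating the
#' fast contribution).
#'
#' @param s a [spectrum].
#' @param h nonnegative coefficient per group (e.g. pSv cm^2), aligned to the
#'   grid of `s`.
#' @param e_star threshold energy (MeV).
#' @return List with `total` and `fraction_above`.
#' @export
dose_equivalent <- function(s, h, e_star = 0.5) {
  stopifnot(inherits(s, "spectrum"))
  h <- as.numeric(h)
  if (length(h) != length(s$values) || any(!is.finite(h)) || any(h < 0)) {
    stop("'h' must be nonnegative coefficients aligned to the spectrum grid",
         call. = FALSE)
  }
  total <- sum(h * s$values)
  if (total <= 0) {
    stop("total dose equivalent is zero; the fast fraction is undefined",
         call. = FALSE)
  }
  above <- s$grid$group_energies >= e_star
  list(total = total, fraction_above = sum(h[above] * s$values[above]) / total)
}
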