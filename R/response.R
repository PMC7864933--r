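# Moderator configurations, response functions, forward model ----------------

#' Moderator sphere set
#'
#' The set of moderator configurations of the multi-directional spectrometer:
#' diameter 0 denotes the bare cube, the remaining entries are polyethylene
#' sphere diameters in inches. The default is the bare cube plus the eight
#' spheres of 2, 3, 4, 5, 6, 8, 10 and 12 inch diameter, spheres wrapped in a
#' 0.5 mm cadmium sheet (the bare cube is not).
#'
#' @param diameters nonnegative, strictly increasing diameters in inches;
#'   0 = bare cube.
#' @param cd_covered logical per configuration: covered by a cadmium sheet.
#'   Defaults to `diameters > 0`.
#' @return An object of class `sphere_set`.
#' @export
sphere_set <- function(diameters = c(0, 2, 3, 4, 5, 6, 8, 10, 12),
                       cd_covered = diameters > 0) {
  diameters <- as.numeric(diameters)
  if (length(diameters) < 1L || any(!is.finite(diameters)) || any(diameters < 0)) {
    stop("diameters must be finite and >= 0 (inches)", call. = FALSE)
  }
  if (any(diff(diameters) <= 0)) {
    stop("diameters must be strictly increasing (and unique)", call. = FALSE)
  }
  cd_covered <- as.logical(cd_covered)
  if (length(cd_covered) != length(diameters) || any(is.na(cd_covered))) {
    stop("'cd_covered' must be a logical flag per configuration", call. = FALSE)
  }
  structure(list(diameters = diameters, cd_covered = cd_covered),
            class = "sphere_set")
}

#' @export
print.sphere_set <- function(x, ...) {
  lab <- ifelse(x$diameters == 0, "bare", paste0(x$diameters, "in"))
  lab <- ifelse(x$cd_covered, paste0(lab, "+Cd"), lab)
  cat("<sphere_set>", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

config_labels <- function(ss) {
  ifelse(ss$diameters == 0, "bare", paste0(format(ss$diameters, trim = TRUE), "in"))
}

#' Parameters of the parametric response family
#'
#' Measured or Monte-Carlo sphere response functions are facility specific and
#' can be loaded from CSV ([read_response_csv()]); this parametric family is a
#' self-contained default with the qualitative features of moderator-sphere
#' responses: a log-normal (in energy) sensitivity bump whose peak energy
#' grows exponentially with sphere diameter, an amplitude mildly increasing
#' with diameter, a Maxwell-shaped thermal term for the bare cube, and a hard
#' cadmium cutoff for covered configurations.
#'
#' @param e_thermal peak energy of the bare-cube thermal term (MeV).
#' @param thermal_amp amplitude of the thermal term.
#' @param peak_e0 bump peak energy at diameter 0 (MeV).
#' @param peak_growth exponential growth rate of the bump peak energy per inch
#'   of diameter; the default puts the 12-inch peak near 8 MeV.
#' @param sigma_ln log-energy width of the bump.
#' @param amp0,amp_slope bump amplitude `amp0 + amp_slope * diameter`.
#' @param cd_cutoff cadmium cutoff energy (MeV); covered configurations have
#'   zero response below it.
#' @return A list of class `response_params`.
#' @export
response_params <- function(e_thermal = 2.5e-8, thermal_amp = 1,
                            peak_e0 = 2.5e-8, peak_growth = log(3.2e8) / 12,
                            sigma_ln = 2, amp0 = 1, amp_slope = 0.05,
                            cd_cutoff = 5e-7) {
  assert_scalar_number(e_thermal, "e_thermal", positive = TRUE)
  assert_scalar_number(thermal_amp, "thermal_amp", nonneg = TRUE)
  assert_scalar_number(peak_e0, "peak_e0", positive = TRUE)
  assert_scalar_number(peak_growth, "peak_growth", positive = TRUE)
  assert_scalar_number(sigma_ln, "sigma_ln", positive = TRUE)
  assert_scalar_number(amp0, "amp0", positive = TRUE)
  assert_scalar_number(amp_slope, "amp_slope", nonneg = TRUE)
  assert_scalar_number(cd_cutoff, "cd_cutoff", positive = TRUE)
  structure(list(e_thermal = e_thermal, thermal_amp = thermal_amp,
                 peak_e0 = peak_e0, peak_growth = peak_growth,
                 sigma_ln = sigma_ln, amp0 = amp0, amp_slope = amp_slope,
                 cd_cutoff = cd_cutoff),
            class = "response_params")
}

#' Parametric response of one configuration
#'
#' Reading per unit fluence of monoenergetic neutrons of energy `energy` for a
#' moderator of diameter `diameter`; vectorized over `energy`. See
#' [response_params()] for the functional form.
#'
#' @param diameter moderator diameter in inches (0 = bare cube).
#' @param energy neutron energy (MeV), vectorized.
#' @param params a [response_params()] list.
#' @param cd_covered apply the cadmium cutoff.
#' @return Nonnegative response values, same length as `energy`.
#' @export
#' @examples
#' p <- response_params()
#' parametric_response(0, 2.5e-8, p)              # bare-cube thermal maximum
#' parametric_response(12, c(1, 8, 100), p)       # 12-inch bump peaks near 8 MeV
parametric_response <- function(diameter, energy, params = response_params(),
                                cd_covered = diameter > 0) {
  assert_scalar_number(diameter, "diameter", nonneg = TRUE)
  if (!is.numeric(energy) || any(!is.finite(energy)) || any(energy <= 0)) {
    stop("'energy' must be finite and > 0 (MeV)", call. = FALSE)
  }
  p <- params
  e_peak <- p$peak_e0 * exp(p$peak_growth * diameter)
  r <- (p$amp0 + p$amp_slope * diameter) *
    exp(-0.5 * ((log(energy) - log(e_peak)) / p$sigma_ln)^2)
  if (diameter == 0) {
    r <- r + p$thermal_amp * (energy / p$e_thermal) * exp(1 - energy / p$e_thermal)
  }
  if (isTRUE(cd_covered)) r[energy < p$cd_cutoff] <- 0
  r
}

#' Response matrix for a sphere set on a grid
#'
#' Row i holds the response of configuration i evaluated at the grid's group
#' energies: the matrix R of the discretized forward relation `A = R %*% phi`.
#'
#' @param ss a [sphere_set()].
#' @param grid an [energy_grid].
#' @param params a [response_params()] list.
#' @return An object of class `response_matrix` with fields `sphere_set`,
#'   `grid` and the `n_config x n_group` matrix `values`.
#' @export
build_response_matrix <- function(ss = sphere_set(), grid = build_output_grid(),
                                  params = response_params()) {
  stopifnot(inherits(ss, "sphere_set"), inherits(grid, "energy_grid"))
  e <- grid$group_energies
  values <- t(vapply(seq_along(ss$diameters), function(i) {
    parametric_response(ss$diameters[i], e, params, cd_covered = ss$cd_covered[i])
  }, numeric(length(e))))
  dimnames(values) <- list(config_labels(ss), NULL)
  response_matrix(ss, grid, values)
}

#' Assemble a response matrix from raw values
#'
#' @param ss a [sphere_set()].
#' @param grid an [energy_grid].
#' @param values nonnegative matrix, one row per configuration, one column per
#'   energy group.
#' @return A `response_matrix`.
#' @export
response_matrix <- function(ss, grid, values) {
  stopifnot(inherits(ss, "sphere_set"), inherits(grid, "energy_grid"))
  values <- as.matrix(values)
  if (nrow(values) != length(ss$diameters) ||
      ncol(values) != length(grid$group_energies)) {
    stop("response matrix shape must be n_configurations x n_groups", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("response values must be finite and >= 0", call. = FALSE)
  }
  structure(list(sphere_set = ss, grid = grid, values = values),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d configurations x %d groups\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-configuration detector readings
#'
#' One thermal-detector reading (fluence-equivalent, n cm^-2 MU^-1) per
#' moderator configuration: the vector A of `A = R %*% phi`.
#'
#' @param ss a [sphere_set()].
#' @param values nonnegative reading per configuration.
#' @param sd optional per-reading standard deviation.
#' @param meta free-form provenance list.
#' @return An object of class `detector_readings`.
#' @export
detector_readings <- function(ss, values, sd = NULL, meta = list()) {
  stopifnot(inherits(ss, "sphere_set"))
  values <- as.numeric(values)
  if (length(values) != length(ss$diameters)) {
    stop("one reading per moderator configuration is required", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("readings must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(values) || any(!is.finite(sd)) || any(sd < 0)) {
      stop("'sd' must be a nonnegative vector, one per configuration", call. = FALSE)
    }
  }
  structure(list(sphere_set = ss, values = values, sd = sd, meta = meta),
            class = "detector_readings")
}

#' @export
print.detector_readings <- function(x, ...) {
  cat("<detector_readings>\n")
  print(stats::setNames(x$values, config_labels(x$sphere_set)))
  invisible(x)
}

#' Fold a spectrum through a response matrix
#'
#' The forward model: reading of configuration i is
#' `sum_g R[i, g] * phi[g]`, exactly linear in the spectrum.
#'
#' @param R a `response_matrix`.
#' @param s a [spectrum] on the same grid.
#' @return [detector_readings()] (noise free, no `sd`).
#' @export
fold <- function(R, s) {
  stopifnot(inherits(R, "response_matrix"), inherits(s, "spectrum"))
  stop_if_grid_mismatch(R$grid, s$grid, "spectrum")
  detector_readings(R$sphere_set, as.vector(R$values %*% s$values))
}

# Response-matrix CSV ---------------------------------------------------------

#' Write / read a response matrix as CSV
#'
#' Format: header `diameter_in,E1,...,Em` with the group energies in MeV,
#' then one row per configuration, first field the diameter in inches
#' (0 = bare cube). Values are written at full double precision so a
#' write-read round trip is lossless. On read, `cd_covered` is set to
#' `diameter > 0` (the flag only matters when generating parametric
#' responses, not when folding or unfolding).
#'
#' @param R a `response_matrix`.
#' @param path file path.
#' @return `write_response_csv()` returns `path` invisibly;
#'   `read_response_csv()` returns a `response_matrix`.
#' @export
write_response_csv <- function(R, path) {
  stopifnot(inherits(R, "response_matrix"))
  header <- paste(c("diameter_in", sprintf("%.17g", R$grid$group_energies)),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(R$values)), function(i) {
    paste(c(sprintf("%.17g", R$sphere_set$diameters[i]),
            sprintf("%.17g", R$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("response CSV needs a header and at least one row", call. = FALSE)
  fields <- strsplit(lines, ",", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "diameter_in") {
    stop("response CSV header must start with 'diameter_in'", call. = FALSE)
  }
  energies <- suppressWarnings(as.numeric(header[-1]))
  if (any(is.na(energies))) {
    stop("response CSV header: non-numeric energy in column ",
         which(is.na(energies))[1] + 1L, call. = FALSE)
  }
  if (any(diff(energies) <= 0)) {
    stop("response CSV header: energies must be strictly increasing (column ",
         which(diff(energies) <= 0)[1] + 2L, ")", call. = FALSE)
  }
  m <- length(energies)
  body <- fields[-1]
  vals <- matrix(NA_real_, length(body), m)
  diam <- numeric(length(body))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != m + 1L) {
      stop(sprintf("response CSV row %d has %d fields, expected %d",
                   i + 1L, length(row), m + 1L), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(row))
    if (any(is.na(num))) {
      stop(sprintf("response CSV row %d: non-numeric value in column %d",
                   i + 1L, which(is.na(num))[1]), call. = FALSE)
    }
    diam[i] <- num[1]
    vals[i, ] <- num[-1]
  }
  response_matrix(sphere_set(diam), energy_grid(energies, label = basename(path)),
                  vals)
}
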