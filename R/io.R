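# Spectrum CSV, campaign JSON, coefficient CSV -------------------------------

#' Write / read a spectrum as CSV
#'
#' Columns `energy_MeV,fluence` and optionally `sd`; energies strictly
#' ascending, fluences nonnegative. Values are written with nine significant
#' digits, so a write-read round trip is lossless at that precision.
#'
#' @param s a [spectrum].
#' @param path file path.
#' @return `write_spectrum_csv()` returns `path` invisibly;
#'   `read_spectrum_csv()` returns a [spectrum] (grid labelled by file name).
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  has_sd <- !is.null(s$sd)
  header <- if (has_sd) "energy_MeV,fluence,sd" else "energy_MeV,fluence"
  rows <- vapply(seq_along(s$values), function(i) {
    f <- sprintf("%.9g", c(s$grid$group_energies[i], s$values[i],
                           if (has_sd) s$sd[i]))
    paste(f, collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("energy_MeV", "fluence") %in% names(d))) {
    stop("spectrum CSV needs columns 'energy_MeV' and 'fluence'", call. = FALSE)
  }
  e <- suppressWarnings(as.numeric(d$energy_MeV))
  v <- suppressWarnings(as.numeric(d$fluence))
  bad <- which(!is.finite(e) | !is.finite(v))
  if (length(bad)) {
    stop("spectrum CSV row ", bad[1], ": non-numeric value", call. = FALSE)
  }
  if (any(diff(e) <= 0)) {
    stop("spectrum CSV row ", which(diff(e) <= 0)[1] + 1L,
         ": energies must be strictly ascending (no duplicates)", call. = FALSE)
  }
  if (any(v < 0)) {
    stop("spectrum CSV row ", which(v < 0)[1], ": negative fluence", call. = FALSE)
  }
  sd <- NULL
  if ("sd" %in% names(d)) {
    sd <- suppressWarnings(as.numeric(d$sd))
    if (any(!is.finite(sd) | sd < 0)) {
      stop("spectrum CSV row ", which(!is.finite(sd) | sd < 0)[1],
           ": invalid sd", call. = FALSE)
    }
  }
  spectrum(energy_grid(e, label = basename(path)), v, sd = sd,
           meta = list(path = path))
}

#' Write / read a cube campaign as JSON
#'
#' The JSON object carries the location, exposure, moderator diameters and
#' cadmium flags, plus one entry per side A-F with the per-configuration
#' readings and, when available, their standard deviations. Missing `sd`
#' stays absent (it is not coerced to zero). Numbers round-trip at full
#' double precision.
#'
#' @param c a [cube_campaign()].
#' @param path file path.
#' @return `write_campaign_json()` returns `path` invisibly;
#'   `read_campaign_json()` returns a [cube_campaign()].
#' @export
write_campaign_json <- function(c, path) {
  stopifnot(inherits(c, "cube_campaign"))
  sides <- lapply(c$sides, function(r) {
    out <- list(values = r$values)
    if (!is.null(r$sd)) out$sd <- r$sd
    out
  })
  payload <- list(
    location = c$location,
    exposure = as.list(c$exposure),
    diameters_in = c$sphere_set$diameters,
    cd_covered = c$sphere_set$cd_covered,
    sides = sides
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_campaign_json
#' @export
read_campaign_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$diameters_in)) stop("campaign JSON: missing 'diameters_in'", call. = FALSE)
  ss <- sphere_set(as.numeric(p$diameters_in),
                   as.logical(p$cd_covered %||% (p$diameters_in > 0)))
  nd <- length(ss$diameters)
  for (lab in SIDE_LABELS) {
    if (is.null(p$sides[[lab]])) stop("campaign JSON: missing side ", lab, call. = FALSE)
  }
  sides <- lapply(SIDE_LABELS, function(lab) {
    entry <- p$sides[[lab]]
    vals <- as.numeric(entry$values)
    if (length(vals) != nd) {
      stop(sprintf("campaign JSON: side %s has %d readings, expected %d",
                   lab, length(vals), nd), call. = FALSE)
    }
    sd <- if (!is.null(entry$sd)) as.numeric(entry$sd) else NULL
    detector_readings(ss, vals, sd = sd)
  })
  names(sides) <- SIDE_LABELS
  exposure <- unlist(p$exposure %||% list(Gy = NA_real_, MU = NA_real_))
  cube_campaign(sides, location = p$location %||% "", exposure = exposure)
}

#' Read grid-aligned dose-coefficient CSV
#'
#' Columns `energy_MeV,h`; the energies must match the grid (relative 1e-6).
#' Coefficient tables are facility/user supplied; a flat demonstration table
#' aligned to the 25-group output grid ships under `extdata`.
#'
#' @param path file path.
#' @param grid the [energy_grid] the coefficients must align to.
#' @return Numeric vector of coefficients, one per group.
#' @export
#' @examples
#' h <- read_coefficients_csv(
#'   system.file("extdata", "h_flat_demo.csv", package = "pnspec"),
#'   build_output_grid())
read_coefficients_csv <- function(path, grid) {
  stopifnot(inherits(grid, "energy_grid"))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("energy_MeV", "h") %in% names(d))) {
    stop("coefficient CSV needs columns 'energy_MeV' and 'h'", call. = FALSE)
  }
  e <- as.numeric(d$energy_MeV)
  g <- grid$group_energies
  if (length(e) != length(g) || any(abs(e - g) > 1e-6 * pmax(g, 1e-300))) {
    stop("coefficient energies do not align with the target grid", call. = FALSE)
  }
  h <- as.numeric(d$h)
  if (any(!is.finite(h) | h < 0)) {
    stop("coefficients must be finite and >= 0", call. = FALSE)
  }
  h
}
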