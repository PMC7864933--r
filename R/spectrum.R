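# Spectra: group fluences on an energy grid ----------------------------------

#' Construct a spectrum
#'
#' A `spectrum` holds one group fluence per energy group of a grid (units
#' n cm^-2 MU^-1, or dimensionless when normalized), with an optional per-group
#' standard deviation. Group fluences are bin integrals of the underlying
#' fluence density, so totals are plain sums.
#'
#' @param grid an [energy_grid].
#' @param values numeric vector of group fluences, one per group, all >= 0.
#' @param sd optional per-group standard deviation (same length, all >= 0).
#' @param meta free-form provenance list.
#' @return An object of class `spectrum`.
#' @export
#' @examples
#' g <- energy_grid(c(1, 3))
#' s <- spectrum(g, c(2, 2))
#' mean_energy(s)  # 2 MeV
spectrum <- function(grid, values, sd = NULL, meta = list()) {
  stopifnot(inherits(grid, "energy_grid"))
  values <- as.numeric(values)
  if (length(values) != length(grid$group_energies)) {
    stop("length(values) must equal the number of energy groups", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("group fluences must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(values) || any(!is.finite(sd)) || any(sd < 0)) {
      stop("'sd' must be a nonnegative vector matching the grid length", call. = FALSE)
    }
  }
  structure(list(grid = grid, values = values, sd = sd, meta = meta),
            class = "spectrum")
}

#' Total fluence of a spectrum
#'
#' @param s a [spectrum].
#' @return Sum of the group fluences, in the units of `values`.
#' @export
total_fluence <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  sum(s$values)
}

#' Fluence-weighted mean energy
#'
#' `sum(E_g * phi_g) / sum(phi_g)` over the groups; undefined for a spectrum
#' with zero total fluence.
#'
#' @param s a [spectrum].
#' @return Mean energy in MeV.
#' @export
mean_energy <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  tot <- sum(s$values)
  if (tot <= 0) {
    stop("mean energy is undefined for a spectrum with zero total fluence",
         call. = FALSE)
  }
  sum(s$grid$group_energies * s$values) / tot
}

#' Rebin a spectrum onto another grid
#'
#' Redistributes group fluences by fractional overlap of the log-energy bins
#' (bin edges from [grid_edges()]), i.e. assuming the fluence within a source
#' bin is flat per unit lethargy. Total fluence is conserved whenever the
#' target grid covers the source range; fluence falling outside the target
#' edges is dropped. Per-group standard deviations, when present, are
#' propagated in quadrature with the same overlap fractions.
#'
#' @param s a [spectrum].
#' @param target target [energy_grid]; its range must overlap the source.
#' @return A [spectrum] on `target`.
#' @export
rebin <- function(s, target) {
  stopifnot(inherits(s, "spectrum"), inherits(target, "energy_grid"))
  if (grids_compatible(s$grid, target)) {
    return(spectrum(target, s$values, sd = s$sd, meta = s$meta))
  }
  ls <- log(grid_edges(s$grid))
  lt <- log(grid_edges(target))
  if (ls[1] >= lt[length(lt)] || lt[1] >= ls[length(ls)]) {
    stop("cannot rebin: source and target energy ranges are disjoint",
         call. = FALSE)
  }
  ns <- length(ls) - 1L
  nt <- length(lt) - 1L
  # overlap fraction of source bin i assigned to target bin j
  lo <- pmax(matrix(ls[-(ns + 1L)], ns, nt), matrix(lt[-(nt + 1L)], ns, nt, byrow = TRUE))
  hi <- pmin(matrix(ls[-1L], ns, nt), matrix(lt[-1L], ns, nt, byrow = TRUE))
  f <- pmax(hi - lo, 0) / (ls[-1L] - ls[-(ns + 1L)])
  vals <- as.vector(crossprod(f, s$values))
  sd <- if (!is.null(s$sd)) sqrt(as.vector(crossprod(f^2, s$sd^2))) else NULL
  spectrum(target, vals, sd = sd, meta = s$meta)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d groups, total fluence %s, mean energy %s MeV\n",
              length(x$values), fmt_e(sum(x$values)),
              if (sum(x$values) > 0) fmt_e(mean_energy(x)) else "NA"))
  invisible(x)
}

#' Spectrum as a data frame
#'
#' @param x a [spectrum].
#' @param ... unused.
#' @return `data.frame` with columns `energy_MeV`, `fluence` and, when
#'   present, `sd`.
#' @export
as.data.frame.spectrum <- function(x, ...) {
  d <- data.frame(energy_MeV = x$grid$group_energies, fluence = x$values)
  if (!is.null(x$sd)) d$sd <- x$sd
  d
}
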