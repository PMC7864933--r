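# Energy grids ---------------------------------------------------------------

# The 25 representative group energies (MeV) of the standard unfolded output,
# thermal (1.03e-9 MeV) to fast (10.3 MeV).
OUTPUT_GRID_ENERGIES <- c(
  1.03e-09, 5.78e-09, 1.87e-08, 3.28e-08, 5.78e-08,
  1.03e-07, 3.28e-07, 1.03e-06, 3.28e-06, 1.03e-05,
  3.28e-05, 1.03e-04, 3.28e-04, 1.03e-03, 3.28e-03,
  1.03e-02, 3.28e-02, 5.78e-02, 1.03e-01, 1.87e-01,
  3.28e-01, 5.78e-01, 1.03e+00, 1.87e+00, 1.03e+01
)

#' Construct an energy-group grid
#'
#' An `energy_grid` is an ordered set of representative neutron energies, one
#' per energy group, shared by spectra and response matrices. Energies must be
#' strictly increasing and positive; at least two groups are required.
#'
#' @param group_energies numeric vector of representative group energies (MeV).
#' @param label optional text label.
#' @return An object of class `energy_grid` with fields `group_energies` and
#'   `label`.
#' @seealso [build_output_grid()], [build_training_grid()], [grid_edges()]
#' @export
#' @examples
#' energy_grid(c(1e-8, 1e-6, 1e-2, 1), label = "toy")
energy_grid <- function(group_energies, label = "") {
  if (!is.numeric(group_energies) || length(group_energies) < 2L) {
    stop("an energy grid needs at least 2 numeric group energies", call. = FALSE)
  }
  e <- as.numeric(group_energies)
  if (any(!is.finite(e)) || any(e <= 0)) {
    stop("group energies must be finite and > 0 (MeV)", call. = FALSE)
  }
  if (any(diff(e) <= 0)) {
    stop("group energies must be strictly increasing", call. = FALSE)
  }
  structure(list(group_energies = e, label = as.character(label)[1]),
            class = "energy_grid")
}

#' Standard 25-group output grid
#'
#' The grid on which unfolded photoneutron spectra are reported: 25
#' representative energies from 1.03e-9 to 10.3 MeV.
#'
#' @return An [energy_grid] with 25 groups.
#' @export
#' @examples
#' g <- build_output_grid()
#' length(g$group_energies)  # 25
build_output_grid <- function() {
  energy_grid(OUTPUT_GRID_ENERGIES, label = "output-25")
}

#' Logarithmically spaced training grid
#'
#' Builds the grid used for unfolder training data: `n_groups` energies spaced
#' geometrically between `e_min` and `e_max` (endpoints included). The default
#' spans thermal energies to 630 MeV in sixty groups.
#'
#' @param n_groups number of groups (>= 2).
#' @param e_min,e_max grid endpoints in MeV, `0 < e_min < e_max`.
#' @return An [energy_grid].
#' @export
#' @examples
#' build_training_grid()          # 60 groups, 1e-9 .. 630 MeV
#' build_training_grid(2, 1, 100) # just the endpoints
build_training_grid <- function(n_groups = 60, e_min = 1e-9, e_max = 630) {
  if (!is.numeric(n_groups) || length(n_groups) != 1L || n_groups < 2 ||
      n_groups != round(n_groups)) {
    stop("'n_groups' must be an integer >= 2", call. = FALSE)
  }
  assert_scalar_number(e_min, "e_min", positive = TRUE)
  assert_scalar_number(e_max, "e_max", positive = TRUE)
  if (e_min >= e_max) stop("'e_min' must be < 'e_max'", call. = FALSE)
  e <- exp(seq(log(e_min), log(e_max), length.out = n_groups))
  # guard against round-off at the endpoints
  e[1] <- e_min
  e[n_groups] <- e_max
  energy_grid(e, label = sprintf("train-%d", as.integer(n_groups)))
}

#' Group boundaries of a grid
#'
#' Reconstructs `n + 1` bin edges from the `n` representative energies: inner
#' edges are geometric midpoints of adjacent group energies and the two outer
#' edges extend log-symmetrically, so every representative energy is the
#' geometric center of its bin on a uniform geometric grid.
#'
#' @param grid an [energy_grid].
#' @return Numeric vector of `n + 1` edges (MeV), strictly increasing.
#' @export
grid_edges <- function(grid) {
  stopifnot(inherits(grid, "energy_grid"))
  e <- grid$group_energies
  n <- length(e)
  inner <- sqrt(e[-n] * e[-1])
  c(e[1]^2 / inner[1], inner, e[n]^2 / inner[n - 1])
}

#' @export
print.energy_grid <- function(x, ...) {
  e <- x$group_energies
  cat(sprintf("<energy_grid%s> %d groups, %s .. %s MeV\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(e), fmt_e(e[1]), fmt_e(e[length(e)])))
  invisible(x)
}
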