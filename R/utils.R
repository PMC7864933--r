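# Internal helpers shared across modules.

# Numeric comparison of two grids: same length and energies equal to a
# relative tolerance (serialization at finite precision must still match).
grids_compatible <- function(g1, g2, tol = 1e-9) {
  e1 <- g1$group_energies
  e2 <- g2$group_energies
  length(e1) == length(e2) && all(abs(e1 - e2) <= tol * pmax(abs(e1), abs(e2)))
}

stop_if_grid_mismatch <- function(g1, g2, what = "spectrum") {
  if (!grids_compatible(g1, g2)) {
    stop("energy grid mismatch: ", what, " is defined on a different grid", call. = FALSE)
  }
  invisible(TRUE)
}

same_sphere_set <- function(s1, s2, tol = 1e-9) {
  d1 <- s1$diameters
  d2 <- s2$diameters
  length(d1) == length(d2) && all(abs(d1 - d2) <= tol * pmax(abs(d1), abs(d2), 1))
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) stop("'", name, "' must be > 0", call. = FALSE)
  if (nonneg && x < 0) stop("'", name, "' must be >= 0", call. = FALSE)
  invisible(x)
}

fmt_e <- function(x, digits = 3) formatC(x, format = "e", digits = digits - 1)
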