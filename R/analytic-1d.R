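#' Dirichlet Green's function on (0, L)
#'
#' Kernel of the 1D Poisson problem `-u'' = f` with `u(0) = u(L) = 0`:
#' `G(x, x') = (1 - x'/L) x - max(x - x', 0)`. It vanishes at both ends,
#' is symmetric in its arguments, and gives the displacement response to a
#' unit point force at `x'`.
#'
#' @param x Evaluation points in `[0, L]` (vectorised).
#' @param xp Source location in `(0, L)`.
#' @param L Domain length.
#' @return Kernel values.
#' @export
greens_function <- function(x, xp, L) {
  if (any(x < 0 | x > L)) {
    abort("`x` must lie in [0, L].", class = "woundfem_out_of_domain")
  }
  stopifnot(xp > 0, xp < L)
  (1 - xp / L) * x - pmax(x - xp, 0)
}

#' Continuum (cell-density) closed-form displacement in 1D
#'
#' Displacement caused by a uniform cell density supported on the wound
#' region `(a, b)`: the density gradient concentrates into opposite point
#' forces at the wound edges, so
#' `u2(x) = scale * P * (G(x, a) - G(x, b))`, a continuous piecewise-linear
#' profile vanishing at both domain ends. `scale` carries the density
#' amplitude (e.g. `n = Ns / (b - a)` when the field represents `Ns` cells).
#'
#' @param x Evaluation points in `[0, L]`.
#' @param P Force magnitude per unit density.
#' @param a,b Wound endpoints, `0 < a < b < L`.
#' @param L Domain length.
#' @param scale Density amplitude multiplying the unit-density solution.
#' @return Displacement values.
#' @export
continuum_solution_1d <- function(x, P, a, b, L, scale = 1) {
  stopifnot(0 < a, a < b, b < L)
  scale * P * (greens_function(x, a, L) - greens_function(x, b, L))
}

#' Smoothed-particle closed-form displacement in 1D
#'
#' Exact solution of the Poisson problem forced by a sum of Gaussian force
#' dipoles, one per cell, via superposition of error functions:
#' \deqn{u(x) = C \sum_i \tfrac12\{(x/L - 1)\,\mathrm{erf}(s_i/\sqrt2\sigma)
#'  + (x/L)\,\mathrm{erf}((L - s_i)/\sqrt2\sigma)
#'  - \mathrm{erf}((x - s_i)/\sqrt2\sigma)\}.}
#' Two parameterisations are used in practice: `mode = "analytic"` sets the
#' prefactor `C = P * ds` and the spread to the cell spacing `ds` (the
#' regime in which the dipole sum converges to the continuum profile as
#' `ds -> 0`); `mode = "fem"` sets `C = P` with spread equal to the
#' mollifier width `eps` (the exact solution of the problem the FEM
#' discretises).
#'
#' @param x Evaluation points in `[0, L]`.
#' @param cells A [cells_1d()] configuration (its attribute `P` is used).
#' @param L Domain length.
#' @param spread Gaussian spread: the mollifier width `eps` (`mode = "fem"`)
#'   or the cell spacing `ds` (`mode = "analytic"`).
#' @param mode Parameterisation, see Details.
#' @return Displacement values.
#' @export
sp_solution_1d <- function(x, cells, L, spread, mode = c("fem", "analytic")) {
  mode <- match.arg(mode)
  if (spread <= 0) {
    abort("`spread` must be positive.", class = "woundfem_invalid_parameter")
  }
  stopifnot(nrow(cells) >= 1L)
  P <- cell_P(cells)
  pref <- if (mode == "fem") P else P * spread
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  s <- cells$x
  acc <- numeric(length(x))
  for (si in s) {
    acc <- acc + 0.5 * ((x / L - 1) * erf(si / (sqrt(2) * spread)) +
                          (x / L) * erf((L - si) / (sqrt(2) * spread)) -
                          erf((x - si) / (sqrt(2) * spread)))
  }
  pref * acc
}

#' Piecewise-linear limit displacement in 1D
#'
#' The common limit of the dipole sum (as the cell spacing tends to zero)
#' and the continuum solution with unit density amplitude:
#' `u(x) = P[(x/L - 1/2)(b - a) + (|x - b| - |x - a|)/2]`, i.e. linear on
#' `(0, a)`, `(a, b)` and `(b, L)` with slopes `P(b-a)/L`, `P((b-a)/L - 1)`
#' and `P(b-a)/L` respectively.
#'
#' @inheritParams continuum_solution_1d
#' @return Displacement values.
#' @export
limit_solution_1d <- function(x, P, a, b, L) {
  stopifnot(0 < a, a < b, b < L)
  P * ((x / L - 0.5) * (b - a) + 0.5 * (abs(x - b) - abs(x - a)))
}
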