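#' Gaussian mollifiers
#'
#' A mollifier is a smooth stand-in for the Dirac delta distribution. Here it
#' is a Gaussian of standard deviation `epsilon`: in 1D centred at `mu`, in 2D
#' radially symmetric about `center`. Each biological cell carries one; its
#' spatial derivative (the force dipole) is the regularised point force the
#' cell exerts on the extracellular matrix.
#'
#' @param epsilon Mollifier width (standard deviation), a positive length.
#' @param mu Centre of the 1D mollifier (the cell position).
#' @param center Centre of the 2D mollifier, a numeric vector `c(x, y)`.
#' @return An object of class `mollifier_1d` or `mollifier_2d`.
#' @examples
#' m <- mollifier_1d(0.1, mu = 3.5)
#' gauss_1d(3.5, m)           # peak value 1 / sqrt(2 * pi * 0.1^2)
#' interval_mass_1d(3.4, 3.6, m)  # ~0.6827, the one-sigma mass
#' @export
mollifier_1d <- function(epsilon, mu = 0) {
  check_epsilon(epsilon)
  structure(list(epsilon = epsilon, mu = mu), class = "mollifier_1d")
}

#' @rdname mollifier_1d
#' @export
mollifier_2d <- function(epsilon, center = c(0, 0)) {
  check_epsilon(epsilon)
  stopifnot(is.numeric(center), length(center) == 2L)
  structure(list(epsilon = epsilon, center = as.numeric(center)),
            class = "mollifier_2d")
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    abort("`epsilon` must be a single positive number.",
          class = "woundfem_invalid_parameter")
  }
  invisible(epsilon)
}

#' Evaluate a 1D Gaussian mollifier and its dipole
#'
#' `gauss_1d()` evaluates the mollifier density
#' \eqn{\delta_\varepsilon(x-\mu) = \exp\{-(x-\mu)^2/(2\varepsilon^2)\} /
#' \sqrt{2\pi\varepsilon^2}}; `dipole_1d()` evaluates its derivative
#' \eqn{\delta'_\varepsilon}, the force-dipole kernel, which is odd about
#' `mu` and integrates to zero (a cell pulls equally from both sides).
#'
#' @param x Evaluation points (vectorised).
#' @param m A [mollifier_1d()].
#' @return Numeric vector of densities (nonnegative) or signed dipole values.
#' @export
gauss_1d <- function(x, m) {
  stopifnot(inherits(m, "mollifier_1d"))
  dnorm(x, mean = m$mu, sd = m$epsilon)
}

#' @rdname gauss_1d
#' @export
dipole_1d <- function(x, m) {
  stopifnot(inherits(m, "mollifier_1d"))
  -(x - m$mu) / m$epsilon^2 * dnorm(x, mean = m$mu, sd = m$epsilon)
}

#' Gaussian mass of an interval
#'
#' Exact mass of the 1D mollifier over `[l, r]`,
#' \eqn{\tfrac12[\mathrm{erf}((r-\mu)/\sqrt2\varepsilon) -
#' \mathrm{erf}((l-\mu)/\sqrt2\varepsilon)]}. For `r - mu = -(l - mu) =
#' k * epsilon` this reproduces the empirical-rule masses 0.6827, 0.9545,
#' 0.9973 (k = 1, 2, 3) for any width.
#'
#' @param l,r Interval endpoints, `l <= r` (vectorised pairwise).
#' @param m A [mollifier_1d()].
#' @return Mass in `[0, 1]`.
#' @export
interval_mass_1d <- function(l, r, m) {
  stopifnot(inherits(m, "mollifier_1d"))
  if (any(l > r)) {
    abort("Interval endpoints must satisfy `l <= r`.",
          class = "woundfem_invalid_interval")
  }
  pnorm(r, mean = m$mu, sd = m$epsilon) - pnorm(l, mean = m$mu, sd = m$epsilon)
}

#' Gaussian mass of a ball (2D)
#'
#' The radially symmetric bivariate Gaussian of width `epsilon` puts mass
#' \eqn{1 - \exp\{-R^2/(2\varepsilon^2)\}} on any ball of radius `R` about
#' its centre; the mass tends to 1 as `R` grows, which is what makes the
#' mollifier a valid delta replacement.
#'
#' @param R Ball radius, `R >= 0` (vectorised).
#' @param m A [mollifier_2d()].
#' @return Mass in `[0, 1)`.
#' @export
ball_mass_2d <- function(R, m) {
  stopifnot(inherits(m, "mollifier_2d"))
  if (any(R < 0)) {
    abort("`R` must be nonnegative.", class = "woundfem_invalid_parameter")
  }
  1 - exp(-R^2 / (2 * m$epsilon^2))
}

#' Evaluate the bivariate Gaussian mollifier
#'
#' @param x Matrix of evaluation points, one row per point, columns x/y.
#' @param m A [mollifier_2d()].
#' @return Numeric vector of density values.
#' @export
gauss_2d <- function(x, m) {
  stopifnot(inherits(m, "mollifier_2d"))
  x <- matrix(x, ncol = 2L)
  r2 <- (x[, 1L] - m$center[1L])^2 + (x[, 2L] - m$center[2L])^2
  exp(-r2 / (2 * m$epsilon^2)) / (2 * pi * m$epsilon^2)
}

#' Gaussian mass of a rectangle or triangle (2D)
#'
#' Mass of the bivariate mollifier over a planar region. Axis-aligned
#' rectangles are separable and use two exact interval masses; triangles are
#' integrated by a degree-5 symmetric quadrature rule with adaptive
#' subdivision until the requested absolute tolerance is met.
#'
#' @param region Either a length-4 numeric `c(xmin, xmax, ymin, ymax)` for a
#'   rectangle, or a 3x2 matrix of triangle vertex coordinates.
#' @param m A [mollifier_2d()].
#' @param tol Absolute tolerance for the triangle quadrature (default 1e-10).
#' @return Mass in `[0, 1]` (up to quadrature tolerance).
#' @export
region_mass_2d <- function(region, m, tol = 1e-10) {
  stopifnot(inherits(m, "mollifier_2d"), tol > 0)
  if (is.matrix(region)) {
    stopifnot(nrow(region) == 3L, ncol(region) == 2L)
    area <- abs(signed_area(region))
    if (area == 0) {
      warn("Degenerate (zero-area) region; returning mass 0.")
      return(0)
    }
    tri_gauss_mass(array(region, dim = c(1L, 3L, 2L)) |>
                     aperm_tri(), m$center, m$epsilon, tol)
  } else {
    stopifnot(length(region) == 4L)
    if (region[1L] >= region[2L] || region[3L] >= region[4L]) {
      warn("Degenerate rectangle; returning mass 0.")
      return(0)
    }
    mx <- mollifier_1d(m$epsilon, m$center[1L])
    my <- mollifier_1d(m$epsilon, m$center[2L])
    interval_mass_1d(region[1L], region[2L], mx) *
      interval_mass_1d(region[3L], region[4L], my)
  }
}

# internal: reshape a 1 x 3 x 2 array into the (x1,y1,...,x3,y3) 6-column
# layout used by the vectorised triangle quadrature
aperm_tri <- function(a) {
  matrix(c(a[, 1L, 1L], a[, 1L, 2L], a[, 2L, 1L], a[, 2L, 2L],
           a[, 3L, 1L], a[, 3L, 2L]), ncol = 6L)
}

signed_area <- function(v) {
  ((v[2L, 1L] - v[1L, 1L]) * (v[3L, 2L] - v[1L, 2L]) -
     (v[3L, 1L] - v[1L, 1L]) * (v[2L, 2L] - v[1L, 2L])) / 2
}

# Degree-5 symmetric 7-point triangle rule (barycentric points and weights,
# weights relative to triangle area).
.tri7 <- local({
  a1 <- 0.059715871789770; b1 <- 0.470142064105115
  a2 <- 0.797426985353087; b2 <- 0.101286507323456
  bary <- rbind(
    c(1 / 3, 1 / 3, 1 / 3),
    c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
    c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  w <- c(0.225,
         rep(0.132394152788506, 3L),
         rep(0.125939180544827, 3L))
  list(bary = bary, w = w)
})

# Quadrature estimate of the Gaussian mass over many triangles at once.
# tris: n x 6 matrix (x1,y1,x2,y2,x3,y3); returns length-n vector.
tri7_estimate <- function(tris, center, eps) {
  n <- nrow(tris)
  bary <- .tri7$bary
  w <- .tri7$w
  area <- abs((tris[, 3L] - tris[, 1L]) * (tris[, 6L] - tris[, 2L]) -
                (tris[, 5L] - tris[, 1L]) * (tris[, 4L] - tris[, 2L])) / 2
  acc <- numeric(n)
  for (q in seq_along(w)) {
    px <- bary[q, 1L] * tris[, 1L] + bary[q, 2L] * tris[, 3L] +
      bary[q, 3L] * tris[, 5L]
    py <- bary[q, 1L] * tris[, 2L] + bary[q, 2L] * tris[, 4L] +
      bary[q, 3L] * tris[, 6L]
    r2 <- (px - center[1L])^2 + (py - center[2L])^2
    acc <- acc + w[q] * exp(-r2 / (2 * eps^2))
  }
  acc * area / (2 * pi * eps^2)
}

split4 <- function(tris) {
  m12x <- (tris[, 1L] + tris[, 3L]) / 2; m12y <- (tris[, 2L] + tris[, 4L]) / 2
  m23x <- (tris[, 3L] + tris[, 5L]) / 2; m23y <- (tris[, 4L] + tris[, 6L]) / 2
  m13x <- (tris[, 1L] + tris[, 5L]) / 2; m13y <- (tris[, 2L] + tris[, 6L]) / 2
  rbind(
    cbind(tris[, 1L], tris[, 2L], m12x, m12y, m13x, m13y),
    cbind(m12x, m12y, tris[, 3L], tris[, 4L], m23x, m23y),
    cbind(m13x, m13y, m23x, m23y, tris[, 5L], tris[, 6L]),
    cbind(m12x, m12y, m23x, m23y, m13x, m13y))
}

# Adaptive Gaussian mass over a batch of triangles (same mollifier).
# tris: n x 6; returns total mass summed over the batch per original triangle
# is NOT tracked -- this returns per-triangle masses for the input batch.
tri_gauss_mass <- function(tris, center, eps, tol = 1e-10, max_depth = 24L) {
  n <- nrow(tris)
  out <- numeric(n)
  # active set carries the originating triangle id and its local tolerance
  act <- tris
  ids <- seq_len(n)
  ltol <- rep(tol, n)
  coarse <- tri7_estimate(act, center, eps)
  depth <- 0L
  while (nrow(act) > 0L && depth < max_depth) {
    kids <- split4(act)
    fine_parts <- tri7_estimate(kids, center, eps)
    nf <- nrow(act)
    fine <- fine_parts[seq_len(nf)] + fine_parts[nf + seq_len(nf)] +
      fine_parts[2L * nf + seq_len(nf)] + fine_parts[3L * nf + seq_len(nf)]
    ok <- abs(fine - coarse) <= ltol
    if (any(ok)) {
      sums <- rowsum(fine[ok], ids[ok])
      idx <- as.integer(rownames(sums))
      out[idx] <- out[idx] + sums[, 1L]
    }
    if (all(ok)) break
    bad <- which(!ok)
    sel <- c(bad, nf + bad, 2L * nf + bad, 3L * nf + bad)
    act <- kids[sel, , drop = FALSE]
    ids <- rep(ids[bad], 4L)
    ltol <- rep(ltol[bad] / 4, 4L)
    coarse <- fine_parts[sel]
    depth <- depth + 1L
  }
  if (nrow(act) > 0L && depth >= max_depth) {
    # accept the current coarse estimates; error is below tol in practice
    sums <- rowsum(coarse, ids)
    out[as.integer(rownames(sums))] <- out[as.integer(rownames(sums))] + sums[, 1L]
  }
  out
}
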