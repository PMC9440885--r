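# Shared fixtures: the standard 1D uniform-cell benchmark (domain (0, 7),
# wound (2, 5), 50 cells, P = 0.01, h = 0.07) and quadrature oracles used to
# cross-check the erf-based load assembly.

bench_cells <- function() uniform_cells_1d(2, 5, 50, P = 0.01)
bench_mesh <- function(n_elem = 100L) mesh_1d(7, n_elem)

# continuum Green's-function solution scaled by the mean cell density
bench_u2 <- function(x, scale = 50 / 3) {
  continuum_solution_1d(x, P = 0.01, a = 2, b = 5, L = 7, scale = scale)
}

# quadrature oracle for the 1D SP load: integrate P * sum_i d/dx delta_eps
# against each hat function directly (the non-integrated form)
sp_load_oracle_1d <- function(mesh, cells, eps) {
  P <- attr(cells, "P")
  f <- function(x) {
    acc <- 0
    for (s in cells$x) acc <- acc + dipole_1d(x, mollifier_1d(eps, s))
    P * acc
  }
  vapply(seq_along(mesh$nodes), function(j) {
    xj <- mesh$nodes[j]
    val <- 0
    if (j > 1L) {
      xl <- mesh$nodes[j - 1L]
      val <- val + stats::integrate(function(x) f(x) * (x - xl) / mesh$h,
                                    xl, xj, rel.tol = 1e-12,
                                    abs.tol = 1e-13)$value
    }
    if (j < length(mesh$nodes)) {
      xr <- mesh$nodes[j + 1L]
      val <- val + stats::integrate(function(x) f(x) * (xr - x) / mesh$h,
                                    xj, xr, rel.tol = 1e-12,
                                    abs.tol = 1e-13)$value
    }
    val
  }, numeric(1))
}

# fixed-depth triangle quadrature of a scalar integrand f(x, y) -- used as
# an independent oracle for the 2D Gaussian-dipole loads
quad_tri_fixed <- function(f, v1, v2, v3, depth = 5L) {
  tris <- matrix(c(v1[1], v1[2], v2[1], v2[2], v3[1], v3[2]), nrow = 1L)
  for (k in seq_len(depth)) {
    m12 <- cbind((tris[, 1] + tris[, 3]) / 2, (tris[, 2] + tris[, 4]) / 2)
    m23 <- cbind((tris[, 3] + tris[, 5]) / 2, (tris[, 4] + tris[, 6]) / 2)
    m13 <- cbind((tris[, 1] + tris[, 5]) / 2, (tris[, 2] + tris[, 6]) / 2)
    tris <- rbind(
      cbind(tris[, 1:2, drop = FALSE], m12, m13),
      cbind(m12, tris[, 3:4, drop = FALSE], m23),
      cbind(m13, m23, tris[, 5:6, drop = FALSE]),
      cbind(m12, m23, m13))
  }
  # degree-5 rule on each sub-triangle
  a1 <- 0.059715871789770; b1 <- 0.470142064105115
  a2 <- 0.797426985353087; b2 <- 0.101286507323456
  bary <- rbind(c(1/3, 1/3, 1/3),
                c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
                c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  w <- c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3))
  area <- abs((tris[, 3] - tris[, 1]) * (tris[, 6] - tris[, 2]) -
                (tris[, 5] - tris[, 1]) * (tris[, 4] - tris[, 2])) / 2
  tot <- 0
  for (q in seq_along(w)) {
    px <- bary[q, 1] * tris[, 1] + bary[q, 2] * tris[, 3] + bary[q, 3] * tris[, 5]
    py <- bary[q, 1] * tris[, 2] + bary[q, 2] * tris[, 4] + bary[q, 3] * tris[, 6]
    tot <- tot + sum(w[q] * area * f(px, py))
  }
  tot
}

# oracle for the full 2D SP load vector on a small mesh: integrates
# P * grad(delta_eps) . phi over every triangle (non-integrated form)
sp_load_oracle_2d <- function(mesh, cells, eps, depth = 5L) {
  P <- attr(cells, "P")
  b <- numeric(2L * nrow(mesh$nodes))
  for (k in seq_len(nrow(mesh$triangles))) {
    tri <- mesh$triangles[k, ]
    v <- mesh$nodes[tri, , drop = FALSE]
    det <- (v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
      (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])
    for (vv in 1:3) {
      j1 <- vv %% 3L + 1L; j2 <- (vv + 1L) %% 3L + 1L
      # barycentric coordinate of vertex vv (cyclic order vv, j1, j2)
      phi <- function(x, y) {
        ((v[j1, 2] - v[j2, 2]) * (x - v[j2, 1]) +
           (v[j2, 1] - v[j1, 1]) * (y - v[j2, 2])) / det
      }
      for (i in seq_len(nrow(cells))) {
        cx <- cells$x[i]; cy <- cells$y[i]
        gd <- function(x, y, comp) {
          r2 <- (x - cx)^2 + (y - cy)^2
          d <- exp(-r2 / (2 * eps^2)) / (2 * pi * eps^2)
          if (comp == 1L) -(x - cx) / eps^2 * d else -(y - cy) / eps^2 * d
        }
        bx <- quad_tri_fixed(function(x, y) P * gd(x, y, 1L) * phi(x, y),
                             v[1, ], v[2, ], v[3, ], depth)
        by <- quad_tri_fixed(function(x, y) P * gd(x, y, 2L) * phi(x, y),
                             v[1, ], v[2, ], v[3, ], depth)
        nid <- tri[vv]
        b[2L * nid - 1L] <- b[2L * nid - 1L] + bx
        b[2L * nid] <- b[2L * nid] + by
      }
    }
  }
  b
}
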