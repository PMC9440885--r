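#' L2 norm of a finite-element displacement field
#'
#' Exact element-wise integration of the squared piecewise-linear
#' interpolant (no quadrature error): in 1D
#' \eqn{\int_e u^2 = \tfrac{h}{3}(u_l^2 + u_l u_r + u_r^2)}; in 2D the P1
#' mass matrix of each triangle. Vector fields return the root of the sum
#' of the component squares.
#'
#' @param field A `displacement_field_1d` or `displacement_field_2d`.
#' @return The L2 norm.
#' @export
l2_norm <- function(field) UseMethod("l2_norm")

#' @export
l2_norm.displacement_field_1d <- function(field) {
  u <- field$values
  ul <- u[-length(u)]; ur <- u[-1L]
  sqrt(sum(field$mesh$h * (ul^2 + ul * ur + ur^2) / 3))
}

#' @export
l2_norm.displacement_field_2d <- function(field) {
  sqrt(l2_sq_tri(field$mesh, field$values[, 1L]) +
         l2_sq_tri(field$mesh, field$values[, 2L]))
}

l2_sq_tri <- function(mesh, u) {
  t <- mesh$triangles
  u1 <- u[t[, 1L]]; u2 <- u[t[, 2L]]; u3 <- u[t[, 3L]]
  sum(mesh$areas / 6 * (u1^2 + u2^2 + u3^2 + u1 * u2 + u1 * u3 + u2 * u3))
}

#' H1 norm and seminorm
#'
#' The P1 gradient is constant per element, so the seminorm is exact:
#' 1D \eqn{\sum_e h ((u_r - u_l)/h)^2}; 2D \eqn{\sum_k A_k |\nabla u|^2}
#' summed over components. `h1_norm()` returns
#' \eqn{\sqrt{\|u\|_{L^2}^2 + |u|_{H^1}^2}}.
#'
#' @inheritParams l2_norm
#' @return The norm (or seminorm) value.
#' @export
h1_seminorm <- function(field) UseMethod("h1_seminorm")

#' @export
h1_seminorm.displacement_field_1d <- function(field) {
  sqrt(sum(diff(field$values)^2 / field$mesh$h))
}

#' @export
h1_seminorm.displacement_field_2d <- function(field) {
  g <- tri_gradients(field$mesh)
  t <- field$mesh$triangles
  s <- 0
  for (comp in 1:2) {
    u <- field$values[, comp]
    gx <- g$bx[, 1L] * u[t[, 1L]] + g$bx[, 2L] * u[t[, 2L]] +
      g$bx[, 3L] * u[t[, 3L]]
    gy <- g$by[, 1L] * u[t[, 1L]] + g$by[, 2L] * u[t[, 2L]] +
      g$by[, 3L] * u[t[, 3L]]
    s <- s + sum(field$mesh$areas * (gx^2 + gy^2))
  }
  sqrt(s)
}

#' @rdname h1_seminorm
#' @export
h1_norm <- function(field) {
  sqrt(l2_norm(field)^2 + h1_seminorm(field)^2)
}

#' Root-mean-square nodal error
#'
#' \eqn{\sqrt{\sum_i [u^{exact}(x_i) - u^h(x_i)]^2 / N}} over all `N` mesh
#' nodes -- the discrete error measure used to compare finite-element
#' solutions against closed forms.
#'
#' @param field A `displacement_field_1d`.
#' @param reference Vectorised exact solution, a function of `x`.
#' @return RMS error.
#' @export
rms_error <- function(field, reference) {
  stopifnot(inherits(field, "displacement_field_1d"))
  sqrt(mean((reference(field$mesh$nodes) - field$values)^2))
}

#' Mesh-convergence rate from three nested solutions
#'
#' Interpolates the two coarser solutions onto the finest mesh and returns
#' \eqn{\log_2(\|u^h - u^{h/2}\|_{L^2} / \|u^{h/2} - u^{h/4}\|_{L^2})},
#' the standard differences-of-nested-solutions estimate that needs no
#' exact solution.
#'
#' @param fields List of three displacement fields on nested meshes
#'   (each refinement halving `h`), coarsest first.
#' @return List with `rate` and the two difference norms `d1`, `d2`.
#' @export
convergence_rate <- function(fields) {
  stopifnot(length(fields) == 3L)
  fine <- fields[[3L]]
  on_fine <- function(f) {
    if (inherits(fine, "displacement_field_1d")) {
      displacement_field_1d(fine$mesh, evaluate_1d(f, fine$mesh$nodes))
    } else {
      displacement_field_2d(fine$mesh, evaluate_2d(f, fine$mesh$nodes))
    }
  }
  u1 <- on_fine(fields[[1L]]); u2 <- on_fine(fields[[2L]])
  d1 <- diff_field(u1, u2); d2 <- diff_field(u2, on_fine(fields[[3L]]))
  n1 <- l2_norm(d1); n2 <- l2_norm(d2)
  if (n2 == 0) {
    abort("Zero difference between the two finest solutions; rate undefined.",
          class = "woundfem_undefined_rate")
  }
  list(rate = log2(n1 / n2), d1 = n1, d2 = n2)
}

diff_field <- function(f1, f2) {
  if (inherits(f1, "displacement_field_1d")) {
    displacement_field_1d(f1$mesh, f1$values - f2$values)
  } else {
    displacement_field_2d(f1$mesh, f1$values - f2$values)
  }
}

#' Wound reduction ratio in 1D
#'
#' Percentage shrinkage of the subdomain `(a, b)` under the displacement
#' field: the deformed length is `(b + u(b)) - (a + u(a))`, so the reduction
#' is `100 * (u(a) - u(b)) / (b - a)` and the relative (remaining) ratio is
#' its complement to 100.
#'
#' @param field A `displacement_field_1d`.
#' @param a,b Subdomain endpoints inside the domain.
#' @return A one-row tibble: `original`, `deformed`, `reduction_percent`,
#'   `relative_percent` (summing to 100 with the reduction, exactly).
#' @export
reduction_ratio_1d <- function(field, a, b) {
  stopifnot(a < b)
  ua <- evaluate_1d(field, a); ub <- evaluate_1d(field, b)
  deformed <- (b + ub) - (a + ua)
  if (deformed <= 0) {
    abort("Deformed subdomain has non-positive length.",
          class = "woundfem_inverted_subdomain")
  }
  red <- 100 * (ua - ub) / (b - a)
  tibble(original = b - a, deformed = deformed,
         reduction_percent = red, relative_percent = 100 - red)
}

#' Polygon area (shoelace formula)
#'
#' @param poly `n x 2` matrix of polygon vertices, ordered, not repeating
#'   the first point.
#' @return Signed area (positive for counterclockwise orientation).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Wound area reduction in 2D
#'
#' Shoelace areas of the original and displaced wound boundary polygons;
#' reduction percent is `100 * (A0 - A_def) / A0`. A self-intersecting
#' deformed polygon triggers a warning and the signed area is used.
#'
#' @param original,deformed `n x 2` polygon matrices (ordered, closed
#'   implicitly).
#' @return A one-row tibble as in [reduction_ratio_1d()].
#' @export
area_reduction_2d <- function(original, deformed) {
  a0 <- polygon_area(original)
  ad <- polygon_area(deformed)
  if (sign(ad) != sign(a0)) {
    warn("Deformed polygon orientation flipped; using signed areas.")
  }
  red <- 100 * (abs(a0) - abs(ad)) / abs(a0)
  tibble(original = abs(a0), deformed = abs(ad),
         reduction_percent = red, relative_percent = 100 - red)
}

#' Consistency gap between the two force models
#'
#' Norms of the difference field `v = u_SP - u_den` between the
#' smoothed-particle and cell-density solutions on the same mesh. The gap
#' vanishes as the mollifier width tends to zero when the density is built
#' from the same cells.
#'
#' @param u_sp,u_den Displacement fields on the same mesh.
#' @return A one-row tibble with `l2`, `sup` and `h1` norms of the gap.
#' @export
consistency_gap <- function(u_sp, u_den) {
  same <- if (inherits(u_sp, "displacement_field_1d")) {
    inherits(u_den, "displacement_field_1d") &&
      identical(u_sp$mesh$n_elem, u_den$mesh$n_elem) &&
      isTRUE(all.equal(u_sp$mesh$L, u_den$mesh$L))
  } else {
    inherits(u_den, "displacement_field_2d") &&
      isTRUE(all.equal(u_sp$mesh$nodes, u_den$mesh$nodes))
  }
  if (!same) {
    abort("Fields live on different meshes.",
          class = "woundfem_incompatible_mesh")
  }
  v <- diff_field(u_sp, u_den)
  tibble(l2 = l2_norm(v), sup = max(abs(v$values)), h1 = h1_norm(v))
}
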