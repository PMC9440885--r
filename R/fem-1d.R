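#' P1 stiffness matrix for the 1D Poisson problem
#'
#' Assembles the bilinear form `integral(u' v')` on a uniform mesh with
#' piecewise-linear elements: the classical symmetric tridiagonal operator
#' with interior stencil `(-1/h, 2/h, -1/h)`, before boundary conditions.
#'
#' @param mesh A [mesh_1d()].
#' @return A symmetric sparse `Matrix` of dimension `(n_elem + 1)^2`.
#' @export
assemble_stiffness_1d <- function(mesh) {
  stopifnot(inherits(mesh, "mesh_1d"))
  n <- mesh$n_elem + 1L
  h <- mesh$h
  i <- c(seq_len(n), seq_len(n - 1L), seq_len(n - 1L) + 1L)
  j <- c(seq_len(n), seq_len(n - 1L) + 1L, seq_len(n - 1L))
  d <- c(1 / h, rep(2 / h, n - 2L), 1 / h)
  v <- c(d, rep(-1 / h, 2L * (n - 1L)))
  sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

#' Smoothed-particle load vector (1D)
#'
#' Weak-form right-hand side for the dipole forcing
#' `P * sum_i delta'_eps(x - s_i)`, assembled in the integrated-by-parts
#' form `b_j = -P sum_i integral(delta_eps(x - s_i) phi'_j)`. Because the
#' hat-function derivatives are piecewise constant, each entry is an exact
#' combination of Gaussian interval masses (error functions): no quadrature
#' error enters. The entries sum to zero -- dipoles are self-equilibrated.
#'
#' @param mesh A [mesh_1d()].
#' @param cells A [cells_1d()] configuration strictly inside `(0, L)`.
#' @param epsilon Mollifier width.
#' @return Load vector of length `n_elem + 1`.
#' @export
load_sp_1d <- function(mesh, cells, epsilon) {
  stopifnot(inherits(mesh, "mesh_1d"))
  check_epsilon(epsilon)
  if (any(cells$x <= 0 | cells$x >= mesh$L)) {
    abort("Cell positions must lie strictly inside (0, L).",
          class = "woundfem_out_of_domain")
  }
  P <- cell_P(cells)
  # element Gaussian masses, summed over cells
  cdf <- vapply(cells$x, function(s) pnorm(mesh$nodes, mean = s, sd = epsilon),
                numeric(length(mesh$nodes)))
  M <- rowSums(diff(cdf))                  # length n_elem
  -P / mesh$h * (c(0, M) - c(M, 0))
}

#' Cell-density load vector (1D)
#'
#' Weak-form right-hand side for the continuum forcing `P * dn_c/dx` with a
#' piecewise-constant density: `b_j = -P sum_e n_c(e) phi'_j|_e h`, which is
#' exact. A globally constant density produces zero interior load; each
#' density jump acts as a point force at the jump node.
#'
#' @param mesh A [mesh_1d()].
#' @param density A [density_field_1d()] on the same mesh.
#' @param P Force magnitude.
#' @return Load vector of length `n_elem + 1`.
#' @export
load_density_1d <- function(mesh, density, P) {
  stopifnot(inherits(density, "density_field_1d"))
  if (!identical(density$mesh$n_elem, mesh$n_elem) ||
      !isTRUE(all.equal(density$mesh$L, mesh$L))) {
    abort("Density field lives on a different mesh.",
          class = "woundfem_incompatible_mesh")
  }
  nc <- density$values
  -P * (c(0, nc) - c(nc, 0))
}

#' Solve the constrained 1D system
#'
#' Imposes the homogeneous Dirichlet conditions by row/column elimination
#' (boundary values are exact zeros) and solves the interior tridiagonal
#' system with a sparse direct solve.
#'
#' @param mesh A [mesh_1d()].
#' @param load Load vector from [load_sp_1d()] or [load_density_1d()].
#' @return A `displacement_field_1d`: list with `mesh` and nodal `values`.
#' @export
solve_1d <- function(mesh, load) {
  stopifnot(inherits(mesh, "mesh_1d"), length(load) == mesh$n_elem + 1L)
  K <- assemble_stiffness_1d(mesh)
  n <- mesh$n_elem + 1L
  interior <- 2L:(n - 1L)
  u <- numeric(n)
  u[interior] <- as.numeric(Matrix::solve(K[interior, interior],
                                          load[interior]))
  displacement_field_1d(mesh, u)
}

#' @rdname solve_1d
#' @param values Nodal displacement values (boundary entries must be 0).
#' @export
displacement_field_1d <- function(mesh, values) {
  stopifnot(inherits(mesh, "mesh_1d"), length(values) == mesh$n_elem + 1L)
  structure(list(mesh = mesh, values = as.numeric(values)),
            class = "displacement_field_1d")
}

#' @export
print.displacement_field_1d <- function(x, ...) {
  cat(sprintf("<displacement_field_1d> %d nodes on (0, %g), max |u| = %g\n",
              length(x$values), x$mesh$L, max(abs(x$values))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.displacement_field_1d <- function(x, ...) {
  nodes <- x$mesh$nodes
  u <- x$values
  tibble(x = nodes, u = u)
}

#' Evaluate a 1D displacement field
#'
#' Piecewise-linear interpolation of the nodal values.
#'
#' @param field A `displacement_field_1d`.
#' @param x Evaluation points in `[0, L]`.
#' @return Interpolated displacements.
#' @export
evaluate_1d <- function(field, x) {
  stopifnot(inherits(field, "displacement_field_1d"))
  if (any(x < 0 | x > field$mesh$L)) {
    abort("`x` must lie in [0, L].", class = "woundfem_out_of_domain")
  }
  stats::approx(field$mesh$nodes, field$values, xout = x)$y
}
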