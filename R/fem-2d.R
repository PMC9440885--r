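#' Material parameters for plane-strain elasticity
#'
#' Isotropic Hooke law
#' \eqn{\sigma = \frac{E}{1+\nu}[\epsilon + \mathrm{tr}(\epsilon)
#' \frac{\nu}{1-2\nu} I]} -- the plane-strain form, whose stiffness blows up
#' as `nu -> 0.5` (incompressibility).
#'
#' @param E Young's modulus (`> 0`).
#' @param nu Poisson ratio, `0 <= nu < 0.5`.
#' @return Object of class `elastic_params`.
#' @export
elastic_params <- function(E = 1, nu = 0.49) {
  stopifnot(E > 0)
  if (nu >= 0.5 || nu < 0) {
    abort("`nu` must satisfy 0 <= nu < 0.5.",
          class = "woundfem_incompressibility")
  }
  structure(list(E = E, nu = nu), class = "elastic_params")
}

# 3x3 plane-strain constitutive matrix in Voigt order (xx, yy, xy)
dmatrix_plane_strain <- function(mat) {
  f <- mat$E / ((1 + mat$nu) * (1 - 2 * mat$nu))
  f * matrix(c(1 - mat$nu, mat$nu, 0,
               mat$nu, 1 - mat$nu, 0,
               0, 0, (1 - 2 * mat$nu) / 2), 3L, 3L)
}

# Per-triangle shape-function gradients: list(bx, by) are n_tri x 3 matrices
# with grad phi_i = (bx[, i], by[, i]) on each triangle.
tri_gradients <- function(mesh) {
  n <- mesh$nodes; t <- mesh$triangles
  x <- matrix(n[t, 1L], ncol = 3L)
  y <- matrix(n[t, 2L], ncol = 3L)
  twoA <- 2 * mesh$areas
  bx <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L]) / twoA
  by <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L]) / twoA
  list(bx = bx, by = by)
}

#' Plane-strain P1 stiffness matrix
#'
#' Assembles \eqn{\int_\Omega \sigma(\phi_a) : \nabla\phi_b \, d\Omega} with
#' constant-strain triangles. Degrees of freedom are interleaved
#' (`2*node - 1` for x, `2*node` for y). The operator is symmetric and, before
#' boundary constraints, annihilates rigid translations.
#'
#' @param mesh A [structured_trimesh()].
#' @param mat An [elastic_params()].
#' @return Sparse symmetric matrix of dimension `2 * n_nodes`.
#' @export
assemble_stiffness_2d <- function(mesh, mat) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(mat, "elastic_params"))
  D <- dmatrix_plane_strain(mat)
  g <- tri_gradients(mesh)
  nt <- nrow(mesh$triangles)
  dof <- cbind(2L * mesh$triangles[, 1L] - 1L, 2L * mesh$triangles[, 1L],
               2L * mesh$triangles[, 2L] - 1L, 2L * mesh$triangles[, 2L],
               2L * mesh$triangles[, 3L] - 1L, 2L * mesh$triangles[, 3L])
  # B (3 x 6) per element, K_e = A * B' D B, vectorised over elements:
  # row1 (xx): bx1 0 bx2 0 bx3 0 ; row2 (yy): 0 by1 ... ; row3 (xy): by1 bx1 ...
  B <- array(0, dim = c(nt, 3L, 6L))
  for (i in 1:3) {
    B[, 1L, 2L * i - 1L] <- g$bx[, i]
    B[, 2L, 2L * i] <- g$by[, i]
    B[, 3L, 2L * i - 1L] <- g$by[, i]
    B[, 3L, 2L * i] <- g$bx[, i]
  }
  ii <- jj <- vv <- vector("list", 36L)
  idx <- 0L
  for (a in 1:6) {
    for (b in 1:6) {
      idx <- idx + 1L
      kab <- numeric(nt)
      for (r in 1:3) {
        for (s in 1:3) {
          if (D[r, s] != 0) kab <- kab + B[, r, a] * D[r, s] * B[, s, b]
        }
      }
      ii[[idx]] <- dof[, a]
      jj[[idx]] <- dof[, b]
      vv[[idx]] <- kab * mesh$areas
    }
  }
  ndof <- 2L * nrow(mesh$nodes)
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
               dims = c(ndof, ndof))
}

#' Smoothed-particle load vector (2D)
#'
#' Weak form of the dipole forcing
#' `P * sum_i grad delta_eps(x - s_i)`, assembled in the integrated-by-parts
#' (divergence) form: for the vector hat function of node `n` in direction
#' `d`, the entry is `-P * sum_i sum_k (d phi_n / d x_d)|_k * mass_i(e_k)`
#' with the Gaussian triangle masses computed by adaptive quadrature.
#' Triangles farther than `8 * epsilon` from a cell are skipped (their mass
#' is below 1e-13). The x-entries and y-entries each sum to zero: dipoles
#' carry no net force.
#'
#' @param mesh A [structured_trimesh()].
#' @param cells A [cells_2d()] configuration inside the domain.
#' @param epsilon Mollifier width; a warning is issued when `epsilon`
#'   exceeds a third of the smallest triangle edge, where the per-element
#'   Gaussian masses are no longer close to indicator counts.
#' @param tol Absolute tolerance of the per-triangle Gaussian masses.
#' @return Load vector of length `2 * n_nodes`.
#' @export
load_sp_2d <- function(mesh, cells, epsilon, tol = 1e-10) {
  stopifnot(inherits(mesh, "tri_mesh"))
  check_epsilon(epsilon)
  d <- attr(mesh, "domain")
  if (any(cells$x <= d[1L] | cells$x >= d[2L] |
          cells$y <= d[3L] | cells$y >= d[4L])) {
    abort("Cell positions must lie strictly inside the domain.",
          class = "woundfem_out_of_domain")
  }
  hmin <- min(attr(mesh, "dx"), attr(mesh, "dy"))
  if (epsilon > hmin / 3) {
    warn(sprintf("epsilon = %g exceeds h_min/3 = %g; per-element masses may deviate from counts.",
                 epsilon, hmin / 3))
  }
  P <- cell_P(cells)
  g <- tri_gradients(mesh)
  tri <- mesh$triangles
  tris6 <- cbind(mesh$nodes[tri[, 1L], 1L], mesh$nodes[tri[, 1L], 2L],
                 mesh$nodes[tri[, 2L], 1L], mesh$nodes[tri[, 2L], 2L],
                 mesh$nodes[tri[, 3L], 1L], mesh$nodes[tri[, 3L], 2L])
  cx <- (tris6[, 1L] + tris6[, 3L] + tris6[, 5L]) / 3
  cy <- (tris6[, 2L] + tris6[, 4L] + tris6[, 6L]) / 3
  # circumscribing radius about the centroid, for the far-field cutoff
  rad <- sqrt(pmax((tris6[, 1L] - cx)^2 + (tris6[, 2L] - cy)^2,
                   (tris6[, 3L] - cx)^2 + (tris6[, 4L] - cy)^2,
                   (tris6[, 5L] - cx)^2 + (tris6[, 6L] - cy)^2))
  ndof <- 2L * nrow(mesh$nodes)
  b <- numeric(ndof)
  cutoff <- 8 * epsilon
  for (i in seq_len(nrow(cells))) {
    ctr <- c(cells$x[i], cells$y[i])
    near <- which(sqrt((cx - ctr[1L])^2 + (cy - ctr[2L])^2) - rad <= cutoff)
    if (!length(near)) next
    mass <- tri_gauss_mass(tris6[near, , drop = FALSE], ctr, epsilon, tol)
    for (v in 1:3) {
      nid <- tri[near, v]
      bx_add <- rowsum(-P * g$bx[near, v] * mass, nid)
      by_add <- rowsum(-P * g$by[near, v] * mass, nid)
      ids <- as.integer(rownames(bx_add))
      b[2L * ids - 1L] <- b[2L * ids - 1L] + bx_add[, 1L]
      b[2L * ids] <- b[2L * ids] + by_add[, 1L]
    }
  }
  b
}

#' Cell-density load vector (2D)
#'
#' Weak form of the continuum forcing `P * div(n_c I)` with a piecewise
#' constant density: entry `-P * sum_k n_c(e_k) (d phi_n / d x_d)|_k A(e_k)`,
#' exact since both factors are constant per triangle. Equals the
#' smoothed-particle load in the limit of vanishing mollifier width when the
#' density is built from the same cells.
#'
#' @param mesh A [structured_trimesh()].
#' @param density A [density_field_2d()] on the same mesh.
#' @param P Force magnitude.
#' @return Load vector of length `2 * n_nodes`.
#' @export
load_density_2d <- function(mesh, density, P) {
  stopifnot(inherits(density, "density_field_2d"))
  if (!identical(dim(density$mesh$triangles), dim(mesh$triangles)) ||
      !isTRUE(all.equal(density$mesh$nodes, mesh$nodes))) {
    abort("Density field lives on a different mesh.",
          class = "woundfem_incompatible_mesh")
  }
  g <- tri_gradients(mesh)
  tri <- mesh$triangles
  w <- density$values * mesh$areas
  ndof <- 2L * nrow(mesh$nodes)
  b <- numeric(ndof)
  for (v in 1:3) {
    nid <- tri[, v]
    bx_add <- rowsum(-P * g$bx[, v] * w, nid)
    by_add <- rowsum(-P * g$by[, v] * w, nid)
    ids <- as.integer(rownames(bx_add))
    b[2L * ids - 1L] <- b[2L * ids - 1L] + bx_add[, 1L]
    b[2L * ids] <- b[2L * ids] + by_add[, 1L]
  }
  b
}

#' Solve the constrained 2D system
#'
#' Homogeneous Dirichlet conditions on the whole outer boundary, imposed by
#' row/column elimination (boundary displacements are exact zeros), then a
#' sparse direct solve of the interior block.
#'
#' @param mesh A [structured_trimesh()].
#' @param mat An [elastic_params()].
#' @param load Load vector from [load_sp_2d()] or [load_density_2d()].
#' @return A `displacement_field_2d`: list with `mesh` and an `n_nodes x 2`
#'   matrix `values` of nodal displacements.
#' @export
solve_2d <- function(mesh, mat, load) {
  stopifnot(length(load) == 2L * nrow(mesh$nodes))
  K <- assemble_stiffness_2d(mesh, mat)
  fixed <- sort(c(2L * mesh$boundary_nodes - 1L, 2L * mesh$boundary_nodes))
  free <- setdiff(seq_len(2L * nrow(mesh$nodes)), fixed)
  u <- numeric(2L * nrow(mesh$nodes))
  u[free] <- as.numeric(Matrix::solve(K[free, free], load[free]))
  displacement_field_2d(mesh, cbind(u[c(TRUE, FALSE)], u[c(FALSE, TRUE)]))
}

#' @rdname solve_2d
#' @param values `n_nodes x 2` matrix of nodal displacements.
#' @export
displacement_field_2d <- function(mesh, values) {
  stopifnot(inherits(mesh, "tri_mesh"), nrow(values) == nrow(mesh$nodes),
            ncol(values) == 2L)
  structure(list(mesh = mesh, values = values),
            class = "displacement_field_2d")
}

#' @export
print.displacement_field_2d <- function(x, ...) {
  cat(sprintf("<displacement_field_2d> %d nodes, max |u| = %g\n",
              nrow(x$values), max(sqrt(rowSums(x$values^2)))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.displacement_field_2d <- function(x, ...) {
  nodes <- x$mesh$nodes
  vals <- x$values
  tibble(x = nodes[, 1L], y = nodes[, 2L],
         ux = vals[, 1L], uy = vals[, 2L],
         magnitude = sqrt(vals[, 1L]^2 + vals[, 2L]^2))
}

#' Evaluate a 2D displacement field
#'
#' @param field A `displacement_field_2d`.
#' @param pts `n x 2` matrix of evaluation points inside the domain.
#' @return `n x 2` matrix of interpolated displacements.
#' @export
evaluate_2d <- function(field, pts) {
  stopifnot(inherits(field, "displacement_field_2d"))
  interp_trimesh(field$mesh, field$values, pts)
}

#' Rectangle boundary polyline
#'
#' Samples the boundary of a rectangle counterclockwise with
#' `samples_per_edge` points per edge (corners included once), producing the
#' closed polygon used for wound-boundary tracking.
#'
#' @param rect Rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param samples_per_edge Sample points per edge (default 50).
#' @return `4 * samples_per_edge x 2` matrix, ordered, not repeating the
#'   first point.
#' @export
rect_polyline <- function(rect, samples_per_edge = 50L) {
  n <- as.integer(samples_per_edge)
  stopifnot(n >= 1L)
  tx <- seq(rect[1L], rect[2L], length.out = n + 1L)[-(n + 1L)]
  ty <- seq(rect[3L], rect[4L], length.out = n + 1L)[-(n + 1L)]
  unname(rbind(
    cbind(tx, rect[3L]),
    cbind(rect[2L], ty),
    cbind(seq(rect[2L], rect[1L], length.out = n + 1L)[-(n + 1L)], rect[4L]),
    cbind(rect[1L], seq(rect[4L], rect[3L], length.out = n + 1L)[-(n + 1L)])))
}

#' Deformed wound boundary
#'
#' Maps every sampled boundary point `x` to `x + u(x)` with piecewise-linear
#' interpolation of the displacement field: the contracted interface between
#' wound and undamaged tissue.
#'
#' @param field A `displacement_field_2d`.
#' @param polyline `n x 2` matrix of boundary samples (e.g.
#'   [rect_polyline()]).
#' @return Displaced polyline, same shape.
#' @export
deformed_boundary <- function(field, polyline) {
  polyline + evaluate_2d(field, polyline)
}
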