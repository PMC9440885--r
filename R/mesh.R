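#' Uniform 1D mesh
#'
#' Partition of the interval `(0, L)` into `n_elem` equal elements with
#' nodes `x_1 = 0 < x_2 < ... < x_{n_elem+1} = L`, the grid on which the
#' P1 finite-element problems and the piecewise-constant cell densities live.
#'
#' @param L Domain length.
#' @param n_elem Number of elements (`>= 2`).
#' @return An object of class `mesh_1d` with fields `nodes`, `h`, `L`,
#'   `n_elem`.
#' @export
mesh_1d <- function(L, n_elem) {
  stopifnot(is.numeric(L), L > 0)
  n_elem <- as.integer(n_elem)
  if (n_elem < 2L) {
    abort("`n_elem` must be at least 2.", class = "woundfem_mesh_too_coarse")
  }
  structure(
    list(nodes = seq(0, L, length.out = n_elem + 1L),
         h = L / n_elem, L = L, n_elem = n_elem),
    class = "mesh_1d")
}

#' @export
print.mesh_1d <- function(x, ...) {
  cat(sprintf("<mesh_1d> (0, %g), %d elements, h = %g\n", x$L, x$n_elem, x$h))
  invisible(x)
}

#' Structured triangular mesh of a rectangle
#'
#' Splits an `nx` by `ny` grid of squares into two triangles each along a
#' fixed diagonal (lower-left to upper-right by default), giving a conforming
#' P1 mesh with positively oriented elements.
#'
#' @param domain Rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param nx,ny Number of squares per direction (`>= 2`).
#' @param diagonal `"ur"` (lower-left to upper-right, default) or `"ul"`,
#'   kept as an option for mesh-sensitivity checks.
#' @return An object of class `tri_mesh` with fields `nodes` (n x 2),
#'   `triangles` (m x 3, vertex indices, counterclockwise), `areas`,
#'   `boundary_nodes`, and the generating grid stored as attributes.
#' @export
structured_trimesh <- function(domain, nx, ny, diagonal = c("ur", "ul")) {
  stopifnot(length(domain) == 4L)
  diagonal <- match.arg(diagonal)
  if (domain[1L] >= domain[2L] || domain[3L] >= domain[4L]) {
    abort("Degenerate rectangle.", class = "woundfem_invalid_parameter")
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 2L, ny >= 2L)
  xs <- seq(domain[1L], domain[2L], length.out = nx + 1L)
  ys <- seq(domain[3L], domain[4L], length.out = ny + 1L)
  nodes <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  node_id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  ll <- node_id(i, j); lr <- node_id(i + 1L, j)
  ur <- node_id(i + 1L, j + 1L); ul <- node_id(i, j + 1L)
  if (diagonal == "ur") {
    triangles <- rbind(cbind(ll, lr, ur), cbind(ll, ur, ul))
  } else {
    triangles <- rbind(cbind(ll, lr, ul), cbind(lr, ur, ul))
  }
  v1 <- nodes[triangles[, 1L], , drop = FALSE]
  v2 <- nodes[triangles[, 2L], , drop = FALSE]
  v3 <- nodes[triangles[, 3L], , drop = FALSE]
  areas <- ((v2[, 1L] - v1[, 1L]) * (v3[, 2L] - v1[, 2L]) -
              (v3[, 1L] - v1[, 1L]) * (v2[, 2L] - v1[, 2L])) / 2
  boundary <- which(nodes[, 1L] %in% range(xs) | nodes[, 2L] %in% range(ys))
  structure(
    list(nodes = nodes, triangles = triangles, areas = areas,
         boundary_nodes = boundary),
    class = "tri_mesh",
    domain = domain, nx = nx, ny = ny, diagonal = diagonal,
    dx = diff(domain[1:2]) / nx, dy = diff(domain[3:4]) / ny)
}

#' @export
print.tri_mesh <- function(x, ...) {
  d <- attr(x, "domain")
  cat(sprintf("<tri_mesh> (%g, %g) x (%g, %g), %d nodes, %d triangles\n",
              d[1L], d[2L], d[3L], d[4L], nrow(x$nodes), nrow(x$triangles)))
  invisible(x)
}

# Locate points in a structured tri_mesh. Returns a list with the triangle
# index and barycentric coordinates of each point; points outside the domain
# raise a domain error.
locate_points <- function(mesh, pts) {
  pts <- matrix(pts, ncol = 2L)
  d <- attr(mesh, "domain")
  dx <- attr(mesh, "dx"); dy <- attr(mesh, "dy")
  nx <- attr(mesh, "nx"); ny <- attr(mesh, "ny")
  eps <- 1e-12 * max(abs(d))
  if (any(pts[, 1L] < d[1L] - eps | pts[, 1L] > d[2L] + eps |
          pts[, 2L] < d[3L] - eps | pts[, 2L] > d[4L] + eps)) {
    abort("Point outside the meshed domain.", class = "woundfem_out_of_domain")
  }
  ix <- pmin(pmax(floor((pts[, 1L] - d[1L]) / dx), 0), nx - 1L)
  iy <- pmin(pmax(floor((pts[, 2L] - d[3L]) / dy), 0), ny - 1L)
  xi <- (pts[, 1L] - d[1L]) / dx - ix   # local coords in [0, 1]
  eta <- (pts[, 2L] - d[3L]) / dy - iy
  sq <- iy * nx + ix + 1L               # square index, row-major
  n_sq <- nx * ny
  if (attr(mesh, "diagonal") == "ur") {
    lower <- xi >= eta                   # triangle (ll, lr, ur)
    tri <- ifelse(lower, sq, sq + n_sq)
    # barycentric wrt (ll, lr, ur): l2 = xi - eta, l3 = eta (lower)
    # wrt (ll, ur, ul): l2 = xi, l3 = eta - xi (upper)
    l2 <- ifelse(lower, xi - eta, xi)
    l3 <- ifelse(lower, eta, eta - xi)
  } else {
    lower <- xi + eta <= 1               # triangle (ll, lr, ul)
    tri <- ifelse(lower, sq, sq + n_sq)
    # lower wrt (ll, lr, ul): l2 = xi, l3 = eta
    # upper wrt (lr, ur, ul): l1 = 1 - eta, l2 = xi + eta - 1, l3 = 1 - xi
    l2 <- ifelse(lower, xi, xi + eta - 1)
    l3 <- ifelse(lower, eta, 1 - xi)
  }
  list(triangle = as.integer(tri), l1 = 1 - l2 - l3, l2 = l2, l3 = l3)
}

# Piecewise-linear interpolation of nodal values at arbitrary points.
# values: vector (scalar field) or n x 2 matrix (vector field).
interp_trimesh <- function(mesh, values, pts) {
  loc <- locate_points(mesh, pts)
  tri <- mesh$triangles[loc$triangle, , drop = FALSE]
  if (is.matrix(values)) {
    cbind(loc$l1 * values[tri[, 1L], 1L] + loc$l2 * values[tri[, 2L], 1L] +
            loc$l3 * values[tri[, 3L], 1L],
          loc$l1 * values[tri[, 1L], 2L] + loc$l2 * values[tri[, 2L], 2L] +
            loc$l3 * values[tri[, 3L], 2L])
  } else {
    loc$l1 * values[tri[, 1L]] + loc$l2 * values[tri[, 2L]] +
      loc$l3 * values[tri[, 3L]]
  }
}
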