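#' Cell configurations
#'
#' A cell configuration is a tibble of cell centre positions (`x`, and `y`
#' in 2D) carrying the common force magnitude `P` as an attribute. Each cell
#' exerts a self-equilibrated pulling force (a dipole) of magnitude `P` on
#' the extracellular matrix.
#'
#' @param positions Numeric vector (1D) or two-column matrix / data frame
#'   (2D) of cell centre positions.
#' @param P Force magnitude shared by all cells (dimensionless here).
#' @return A tibble of class `cells_1d` (column `x`, sorted) or `cells_2d`
#'   (columns `x`, `y`) with attribute `P`.
#' @export
cells_1d <- function(positions, P = 1) {
  positions <- sort(as.numeric(positions))
  out <- tibble(x = positions)
  attr(out, "P") <- P
  class(out) <- c("cells_1d", class(out))
  out
}

#' @rdname cells_1d
#' @export
cells_2d <- function(positions, P = 1) {
  positions <- as.data.frame(positions)
  stopifnot(ncol(positions) == 2L)
  names(positions) <- c("x", "y")
  out <- as_tibble(positions)
  attr(out, "P") <- P
  class(out) <- c("cells_2d", class(out))
  out
}

#' @export
print.cells_1d <- function(x, ...) {
  cat(sprintf("<cells_1d> %d cells, P = %g\n", nrow(x), attr(x, "P")))
  NextMethod()
}

#' @export
print.cells_2d <- function(x, ...) {
  cat(sprintf("<cells_2d> %d cells, P = %g\n", nrow(x), attr(x, "P")))
  NextMethod()
}

cell_P <- function(cells) {
  P <- attr(cells, "P")
  if (is.null(P)) 1 else P
}

#' Uniformly spaced cells in a 1D subdomain
#'
#' Places `n` cells equispaced in the wound region `(a, b)`: spacing
#' `ds = (b - a) / n`, first cell at `a + ds / 2`, last at `b - ds / 2`.
#' This is the configuration for which closed-form displacement solutions
#' exist.
#'
#' @param a,b Subdomain endpoints, `0 < a < b`.
#' @param n Number of cells (`>= 1`).
#' @param P Force magnitude.
#' @return A [cells_1d()] configuration with attribute `ds`.
#' @examples
#' cfg <- uniform_cells_1d(2, 5, 50, P = 0.01)  # ds = 0.06
#' head(cfg$x)
#' @export
uniform_cells_1d <- function(a, b, n, P = 1) {
  if (!(a < b)) {
    abort("`a` must be smaller than `b`.", class = "woundfem_invalid_subdomain")
  }
  n <- as.integer(n)
  stopifnot(n >= 1L)
  ds <- (b - a) / n
  out <- cells_1d(a + (seq_len(n) - 0.5) * ds, P = P)
  attr(out, "ds") <- ds
  out
}

#' Piecewise-constant 1D cell-density field
#'
#' @param mesh A [mesh_1d()].
#' @param values Per-element nonnegative densities `n_c(e)`; the implied
#'   per-element count is `h * n_c(e)`.
#' @return Object of class `density_field_1d`.
#' @export
density_field_1d <- function(mesh, values) {
  stopifnot(inherits(mesh, "mesh_1d"), length(values) == mesh$n_elem)
  if (any(values < 0)) {
    abort("Densities must be nonnegative.", class = "woundfem_invalid_density")
  }
  structure(list(mesh = mesh, values = as.numeric(values)),
            class = "density_field_1d")
}

#' @rdname density_field_1d
#' @param mesh2d A [structured_trimesh()].
#' @param values2d Per-triangle densities `n_c(e_k)`; counts are
#'   `A(e_k) * n_c(e_k)`.
#' @export
density_field_2d <- function(mesh2d, values2d) {
  stopifnot(inherits(mesh2d, "tri_mesh"),
            length(values2d) == nrow(mesh2d$triangles))
  if (any(values2d < 0)) {
    abort("Densities must be nonnegative.", class = "woundfem_invalid_density")
  }
  structure(list(mesh = mesh2d, values = as.numeric(values2d)),
            class = "density_field_2d")
}

#' @exportS3Method generics::tidy
tidy.density_field_1d <- function(x, ...) {
  m <- x$mesh
  tibble(element = seq_len(m$n_elem),
         xl = m$nodes[-(m$n_elem + 1L)], xr = m$nodes[-1L],
         measure = m$h, density = x$values, count = m$h * x$values)
}

#' @exportS3Method generics::tidy
tidy.density_field_2d <- function(x, ...) {
  tibble(element = seq_along(x$values), measure = x$mesh$areas,
         density = x$values, count = x$mesh$areas * x$values)
}

#' Cell density from cell positions (1D)
#'
#' Downsampling step of the agent-to-continuum algorithm: counts cells per
#' mesh element and divides by the element length `h`. A cell strictly
#' inside an element contributes one unit to that element; a cell exactly on
#' a shared interior node contributes half a unit to each adjacent element,
#' so the total assigned weight always equals the number of cells.
#'
#' @param cells A [cells_1d()] configuration strictly inside `(0, L)`.
#' @param mesh A [mesh_1d()].
#' @param node_tol Absolute tolerance for deciding that a cell sits on a
#'   node (default `1e-9 * h`).
#' @param node_rule Convention for cells sitting exactly on an interior
#'   node: `"half"` (default; half a unit to each adjacent element, the
#'   convention under which the total weight equals the cell count) or
#'   `"drop"` (node-coincident cells contribute nothing, mimicking counting
#'   codes that bin with strict inequalities on both sides).
#' @return A [density_field_1d()].
#' @export
density_from_positions_1d <- function(cells, mesh, node_tol = 1e-9 * mesh$h,
                                      node_rule = c("half", "drop")) {
  node_rule <- match.arg(node_rule)
  stopifnot(inherits(mesh, "mesh_1d"))
  x <- cells$x
  if (any(x <= node_tol | x >= mesh$L - node_tol)) {
    abort("Cell positions must lie strictly inside (0, L).",
          class = "woundfem_out_of_domain")
  }
  w <- numeric(mesh$n_elem)
  k <- round(x / mesh$h)
  on_node <- abs(x - k * mesh$h) <= node_tol
  # interior-node cells: half a unit to each neighbouring element
  if (node_rule == "half") {
    for (j in k[on_node]) {
      w[j] <- w[j] + 0.5
      w[j + 1L] <- w[j + 1L] + 0.5
    }
  }
  idx <- pmin(pmax(floor(x[!on_node] / mesh$h) + 1L, 1L), mesh$n_elem)
  if (length(idx)) {
    tab <- tabulate(idx, nbins = mesh$n_elem)
    w <- w + tab
  }
  density_field_1d(mesh, w / mesh$h)
}

# round-half-away-from-zero, the bin-count rounding rule
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Cell positions from an analytic density (1D)
#'
#' Continuum-to-agent algorithm: the domain is cut into bins of length `d`,
#' the expected count per bin is the integral of the density over the bin
#' (rounded half away from zero), and that many cell centres are placed in
#' the bin -- equispaced by default, or uniformly at random under the given
#' seed.
#'
#' @param nc Vectorised nonnegative density function of one argument.
#' @param L Domain length; bins tile `(0, L)`.
#' @param d Bin length (`> 0`).
#' @param P Force magnitude attached to the generated cells.
#' @param placement `"equispaced"` (deterministic, default) or `"random"`.
#' @param seed Integer seed used when `placement = "random"`.
#' @return A [cells_1d()] configuration.
#' @examples
#' cfg <- positions_from_density_1d(function(x) 40 * abs(sin(2 * x)),
#'                                  L = 7, d = 0.35)
#' nrow(cfg)
#' @export
positions_from_density_1d <- function(nc, L, d, P = 1,
                                      placement = c("equispaced", "random"),
                                      seed = 1L) {
  placement <- match.arg(placement)
  stopifnot(d > 0, L > 0)
  breaks <- seq(0, L, by = d)
  if (breaks[length(breaks)] < L - 1e-12) breaks <- c(breaks, L)
  probe <- nc(seq(0, L, length.out = 513L))
  if (any(probe < -1e-12)) {
    abort("Density function takes negative values.",
          class = "woundfem_invalid_density")
  }
  counts <- vapply(seq_len(length(breaks) - 1L), function(k) {
    round_half_away(integrate(nc, breaks[k], breaks[k + 1L],
                              rel.tol = 1e-10, abs.tol = 1e-12)$value)
  }, numeric(1))
  if (placement == "random") set.seed(seed)
  pos <- unlist(lapply(seq_along(counts), function(k) {
    n <- counts[k]
    if (n <= 0) return(numeric(0))
    if (placement == "equispaced") {
      breaks[k] + (seq_len(n) - 0.5) / n * (breaks[k + 1L] - breaks[k])
    } else {
      runif(n, breaks[k], breaks[k + 1L])
    }
  }))
  cells_1d(pos, P = P)
}

#' Cell density from cell positions (2D)
#'
#' Counts cells per triangle and divides by the triangle area. A cell
#' strictly inside a triangle contributes one unit; a cell on an edge shared
#' by two triangles contributes half a unit to each; a cell on a vertex
#' contributes, to every incident triangle, the incident angle divided by
#' `2 * pi` -- so interior cells always distribute a total weight of one.
#'
#' @param cells A [cells_2d()] configuration inside the meshed domain.
#' @param mesh A [structured_trimesh()].
#' @param tol Barycentric tolerance for edge/vertex detection.
#' @return A [density_field_2d()].
#' @export
density_from_positions_2d <- function(cells, mesh, tol = 1e-9) {
  stopifnot(inherits(mesh, "tri_mesh"))
  pts <- cbind(cells$x, cells$y)
  d <- attr(mesh, "domain")
  scale <- max(abs(d))
  if (any(pts[, 1L] <= d[1L] + tol * scale | pts[, 1L] >= d[2L] - tol * scale |
          pts[, 2L] <= d[3L] + tol * scale | pts[, 2L] >= d[4L] - tol * scale)) {
    abort("Cell positions must lie strictly inside the domain.",
          class = "woundfem_out_of_domain")
  }
  w <- numeric(nrow(mesh$triangles))
  nodes <- mesh$nodes
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    hit <- containing_triangles(mesh, p, tol)
    nh <- length(hit)
    if (nh == 1L) {
      w[hit] <- w[hit] + 1
    } else if (nh == 2L) {
      w[hit] <- w[hit] + 0.5
    } else {
      # vertex: nearest mesh node, weight by incident angle / 2 pi
      vid <- which.min((nodes[, 1L] - p[1L])^2 + (nodes[, 2L] - p[2L])^2)
      for (t in hit) {
        tri <- mesh$triangles[t, ]
        kk <- which(tri == vid)
        ang <- vertex_angle(nodes[tri[kk], ],
                            nodes[tri[kk %% 3L + 1L], ],
                            nodes[tri[(kk + 1L) %% 3L + 1L], ])
        w[t] <- w[t] + ang / (2 * pi)
      }
    }
  }
  density_field_2d(mesh, w / mesh$areas)
}

# All triangles whose closed hull contains p (barycentric >= -tol).
containing_triangles <- function(mesh, p, tol) {
  loc <- locate_points(mesh, matrix(p, ncol = 2L))
  bmin <- min(loc$l1, loc$l2, loc$l3)
  if (bmin > tol) return(loc$triangle)
  # near an edge or vertex: brute-force barycentric test on candidates
  nodes <- mesh$nodes
  v1 <- nodes[mesh$triangles[, 1L], , drop = FALSE]
  v2 <- nodes[mesh$triangles[, 2L], , drop = FALSE]
  v3 <- nodes[mesh$triangles[, 3L], , drop = FALSE]
  det <- (v2[, 1L] - v1[, 1L]) * (v3[, 2L] - v1[, 2L]) -
    (v3[, 1L] - v1[, 1L]) * (v2[, 2L] - v1[, 2L])
  l2 <- ((p[1L] - v1[, 1L]) * (v3[, 2L] - v1[, 2L]) -
           (v3[, 1L] - v1[, 1L]) * (p[2L] - v1[, 2L])) / det
  l3 <- ((v2[, 1L] - v1[, 1L]) * (p[2L] - v1[, 2L]) -
           (p[1L] - v1[, 1L]) * (v2[, 2L] - v1[, 2L])) / det
  l1 <- 1 - l2 - l3
  which(l1 >= -tol & l2 >= -tol & l3 >= -tol)
}

vertex_angle <- function(v, p1, p2) {
  a <- p1 - v; b <- p2 - v
  acos(pmin(pmax(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1), 1))
}

#' Random non-overlapping cells in a 2D region
#'
#' Places `n` cell centres independently and uniformly in a rectangle,
#' rejection-sampled so that all pairwise distances are at least `min_sep`
#' (cells do not overlap). Reproducible for a fixed seed.
#'
#' @param region Rectangle `c(xmin, xmax, ymin, ymax)` (the wound region).
#' @param n Number of cells.
#' @param min_sep Minimum centre-to-centre separation (default 0.2).
#' @param seed Integer seed.
#' @param P Force magnitude.
#' @param max_tries Attempt budget before declaring the packing infeasible.
#' @return A [cells_2d()] configuration with attribute `min_sep`.
#' @export
random_cells_2d <- function(region, n, min_sep = 0.2, seed = 1L, P = 1,
                            max_tries = 1000L * max(n, 1L)) {
  stopifnot(length(region) == 4L, n >= 0)
  area <- diff(region[1:2]) * diff(region[3:4])
  if (n * pi * (min_sep / 2)^2 > 0.7 * area) {
    abort("Requested packing is infeasible for this `min_sep`.",
          class = "woundfem_infeasible_packing")
  }
  set.seed(seed)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    if (tries >= max_tries) {
      abort("Rejection sampler exceeded its attempt budget.",
            class = "woundfem_infeasible_packing")
    }
    px <- runif(1L, region[1L], region[2L])
    py <- runif(1L, region[3L], region[4L])
    tries <- tries + 1L
    if (placed == 0L ||
        all((xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2 >=
              min_sep^2)) {
      placed <- placed + 1L
      xs[placed] <- px; ys[placed] <- py
    }
  }
  out <- cells_2d(cbind(xs, ys), P = P)
  attr(out, "min_sep") <- min_sep
  out
}

#' Cell positions from an analytic density (2D)
#'
#' Tiles the domain with squares of side `cell_side`, rounds the integral of
#' the density over each square to an integer count, and places that many
#' cell centres uniformly at random (seeded) in the square.
#'
#' @param nc Density function taking an `n x 2` matrix of points and
#'   returning nonnegative values.
#' @param domain Rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param cell_side Side length of the counting squares (default 1).
#' @param seed Integer seed for the in-square placement.
#' @param P Force magnitude.
#' @return A [cells_2d()] configuration.
#' @export
positions_from_density_2d <- function(nc, domain, cell_side = 1, seed = 1L,
                                      P = 1) {
  stopifnot(cell_side > 0, length(domain) == 4L)
  xs <- seq(domain[1L], domain[2L], by = cell_side)
  ys <- seq(domain[3L], domain[4L], by = cell_side)
  if (xs[length(xs)] < domain[2L] - 1e-12) xs <- c(xs, domain[2L])
  if (ys[length(ys)] < domain[4L] - 1e-12) ys <- c(ys, domain[4L])
  gl <- gauss_legendre_16()
  set.seed(seed)
  pos <- list()
  for (i in seq_len(length(xs) - 1L)) {
    for (j in seq_len(length(ys) - 1L)) {
      cnt <- round_half_away(
        square_integral(nc, xs[i], xs[i + 1L], ys[j], ys[j + 1L], gl))
      if (cnt > 0) {
        pos[[length(pos) + 1L]] <-
          cbind(runif(cnt, xs[i], xs[i + 1L]), runif(cnt, ys[j], ys[j + 1L]))
      }
    }
  }
  pts <- if (length(pos)) do.call(rbind, pos) else matrix(numeric(0), ncol = 2L)
  if (any(pts[, 1L] < domain[1L])) stop("internal placement error")
  cells_2d(pts, P = P)
}

# 16-point Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre_16 <- function() {
  x <- c(0.0950125098376374, 0.2816035507792589, 0.4580167776572274,
         0.6178762444026438, 0.7554044083550030, 0.8656312023878318,
         0.9445750230732326, 0.9894009349916499)
  w <- c(0.1894506104550685, 0.1826034150449236, 0.1691565193950025,
         0.1495959888165767, 0.1246289712555339, 0.0951585116824928,
         0.0622535239386479, 0.0271524594117541)
  list(x = c(-rev(x), x), w = c(rev(w), w))
}

square_integral <- function(nc, x0, x1, y0, y1, gl) {
  hx <- (x1 - x0) / 2; hy <- (y1 - y0) / 2
  px <- x0 + hx * (gl$x + 1); py <- y0 + hy * (gl$x + 1)
  pts <- cbind(rep(px, times = length(py)), rep(py, each = length(px)))
  vals <- nc(pts)
  if (any(vals < -1e-12)) {
    abort("Density function takes negative values.",
          class = "woundfem_invalid_density")
  }
  ww <- rep(gl$w, times = length(py)) * rep(gl$w, each = length(px))
  sum(ww * vals) * hx * hy
}
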