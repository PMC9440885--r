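test_that("structured mesh has the expected counts, areas and orientation", {
  mesh <- structured_trimesh(c(0, 1, 0, 1), 2, 2)
  expect_equal(nrow(mesh$nodes), 9L)
  expect_equal(nrow(mesh$triangles), 8L)
  expect_equal(sum(mesh$areas), 1, tolerance = 1e-12)
  expect_true(all(mesh$areas > 0))
  alt <- structured_trimesh(c(0, 1, 0, 1), 2, 2, diagonal = "ul")
  expect_true(all(alt$areas > 0))
  expect_equal(sum(alt$areas), 1, tolerance = 1e-12)
  expect_error(structured_trimesh(c(0, 0, 0, 1), 2, 2),
               class = "woundfem_invalid_parameter")
})

test_that("point location and interpolation reproduce linear fields", {
  for (diag in c("ur", "ul")) {
    mesh <- structured_trimesh(c(-1, 1, -1, 1), 3, 4, diagonal = diag)
    vals <- 2 * mesh$nodes[, 1L] - 0.5 * mesh$nodes[, 2L] + 1
    set.seed(3)
    pts <- cbind(runif(50, -1, 1), runif(50, -1, 1))
    got <- interp_trimesh(mesh, vals, pts)
    expect_equal(got, 2 * pts[, 1L] - 0.5 * pts[, 2L] + 1, tolerance = 1e-12)
  }
})

test_that("plane-strain stiffness is symmetric with rigid modes in its kernel", {
  mesh <- structured_trimesh(c(0, 2, 0, 1), 4, 3)
  K <- assemble_stiffness_2d(mesh, elastic_params(E = 5, nu = 0.3))
  expect_equal(max(abs(K - Matrix::t(K))), 0, tolerance = 1e-12)
  n <- nrow(mesh$nodes)
  expect_lt(max(abs(K %*% rep(c(1, 0), n))), 1e-12)
  expect_lt(max(abs(K %*% rep(c(0, 1), n))), 1e-12)
  expect_error(elastic_params(1, 0.5), class = "woundfem_incompressibility")
})

test_that("patch test: linear displacement reproduced exactly at interior nodes", {
  mesh <- structured_trimesh(c(0, 1, 0, 1), 5, 5)
  mat <- elastic_params(E = 2, nu = 0.49)
  K <- assemble_stiffness_2d(mesh, mat)
  n <- nrow(mesh$nodes)
  ue <- cbind(0.3 * mesh$nodes[, 1L] + 0.1 * mesh$nodes[, 2L],
              -0.2 * mesh$nodes[, 1L] + 0.05 * mesh$nodes[, 2L])
  uv <- as.numeric(t(ue))
  fixed <- sort(c(2L * mesh$boundary_nodes - 1L, 2L * mesh$boundary_nodes))
  free <- setdiff(seq_len(2L * n), fixed)
  sol <- Matrix::solve(K[free, free], -K[free, fixed] %*% uv[fixed])
  expect_lt(max(abs(as.numeric(sol) - uv[free])), 1e-12)
})

test_that("2D SP load is self-equilibrated and matches direct quadrature", {
  mesh <- structured_trimesh(c(0, 1, 0, 1), 4, 4)
  cells <- cells_2d(cbind(0.52, 0.47), P = 2)
  eps <- 0.05
  b <- load_sp_2d(mesh, cells, eps)
  expect_lt(abs(sum(b[c(TRUE, FALSE)])), 1e-12)
  expect_lt(abs(sum(b[c(FALSE, TRUE)])), 1e-12)
  oracle <- sp_load_oracle_2d(mesh, cells, eps)
  expect_lt(max(abs(b - oracle)), 1e-8)
  expect_error(load_sp_2d(mesh, cells_2d(cbind(2, 0.5)), eps),
               class = "woundfem_out_of_domain")
})

test_that("2D SP load respects the half-turn symmetry of a centred cell", {
  # the fixed-diagonal structured mesh is invariant under (x, y) -> (-x, -y)
  mesh <- structured_trimesh(c(-1, 1, -1, 1), 6, 6)
  b <- load_sp_2d(mesh, cells_2d(cbind(0, 0), P = 1), 0.05)
  nodes <- mesh$nodes
  rot <- match(
    paste(round(-nodes[, 1L], 10), round(-nodes[, 2L], 10)),
    paste(round(nodes[, 1L], 10), round(nodes[, 2L], 10)))
  bx <- b[c(TRUE, FALSE)]; by <- b[c(FALSE, TRUE)]
  expect_equal(bx, -bx[rot], tolerance = 1e-10)
  expect_equal(by, -by[rot], tolerance = 1e-10)
})

test_that("2D density load vanishes for constant density and matches SP as eps -> 0", {
  mesh <- structured_trimesh(c(0, 1, 0, 1), 4, 4)
  const <- density_field_2d(mesh, rep(2, nrow(mesh$triangles)))
  b <- load_density_2d(mesh, const, 3)
  interior <- setdiff(seq_len(nrow(mesh$nodes)), mesh$boundary_nodes)
  expect_lt(max(abs(b[c(2L * interior - 1L, 2L * interior)])), 1e-12)
  expect_lt(abs(sum(b[c(TRUE, FALSE)])), 1e-12)
  # one interior cell: SP load approaches the counted-density load
  cells <- cells_2d(cbind(0.55, 0.3), P = 3)
  den <- density_from_positions_2d(cells, mesh)
  bd <- load_density_2d(mesh, den, 3)
  dev <- vapply(c(0.03, 0.015, 0.0075), function(eps) {
    max(abs(load_sp_2d(mesh, cells, eps) - bd))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3L], 1e-3)
})

test_that("2D solve: zero load, half-turn equivariance, linearity", {
  mesh <- structured_trimesh(c(-1, 1, -1, 1), 8, 8)
  mat <- elastic_params(1, 0.3)
  z <- solve_2d(mesh, mat, numeric(2L * nrow(mesh$nodes)))
  expect_equal(max(abs(z$values)), 0)
  b <- load_sp_2d(mesh, cells_2d(cbind(0, 0), P = 1), 0.05)
  u <- solve_2d(mesh, mat, b)
  expect_equal(max(abs(u$values[mesh$boundary_nodes, ])), 0)
  nodes <- mesh$nodes
  rot <- match(
    paste(round(-nodes[, 1L], 10), round(-nodes[, 2L], 10)),
    paste(round(nodes[, 1L], 10), round(nodes[, 2L], 10)))
  expect_equal(u$values[, 1L], -u$values[rot, 1L], tolerance = 1e-8)
  expect_equal(u$values[, 2L], -u$values[rot, 2L], tolerance = 1e-8)
  u2 <- solve_2d(mesh, mat, 2 * b)
  expect_equal(u2$values, 2 * u$values, tolerance = 1e-10)
  # energy positivity
  expect_gt(sum(b * as.numeric(t(u$values))), 0)
})

test_that("deformed boundary interpolates the field and is identity at rest", {
  mesh <- structured_trimesh(c(-2, 2, -2, 2), 8, 8)
  poly <- rect_polyline(c(-1, 1, -1, 1), 10)
  expect_equal(nrow(poly), 40L)
  expect_equal(polygon_area(poly), 4, tolerance = 1e-12)
  zero <- displacement_field_2d(mesh, matrix(0, nrow(mesh$nodes), 2L))
  expect_equal(deformed_boundary(zero, poly), poly)
  # nodal values are reproduced exactly at mesh nodes
  set.seed(9)
  vals <- matrix(rnorm(2L * nrow(mesh$nodes)), ncol = 2L)
  vals[mesh$boundary_nodes, ] <- 0
  f <- displacement_field_2d(mesh, vals)
  inner <- which(abs(mesh$nodes[, 1L]) < 2 & abs(mesh$nodes[, 2L]) < 2)
  got <- evaluate_2d(f, mesh$nodes[inner, ])
  expect_equal(got, vals[inner, ], tolerance = 1e-12)
})
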