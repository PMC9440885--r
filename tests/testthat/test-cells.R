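test_that("uniform 1D cells are equispaced with half-spacing offsets", {
  cfg <- uniform_cells_1d(2, 5, 50, P = 0.01)
  expect_equal(attr(cfg, "ds"), 0.06)
  expect_equal(cfg$x[1L], 2.03)
  expect_equal(cfg$x[50L], 4.97)
  expect_equal(diff(cfg$x), rep(0.06, 49L), tolerance = 1e-12)
  one <- uniform_cells_1d(1, 3, 1)
  expect_equal(one$x, 2)
  expect_error(uniform_cells_1d(5, 2, 10),
               class = "woundfem_invalid_subdomain")
})

test_that("1D position-to-density counting honours interior and node cells", {
  mesh <- mesh_1d(2, 4L)             # h = 0.5
  d <- density_from_positions_1d(cells_1d(c(0.6, 0.7, 0.9)), mesh)
  expect_equal(d$values, c(0, 6, 0, 0))
  # cell exactly on the interior node x = 1
  d2 <- density_from_positions_1d(cells_1d(1), mesh)
  expect_equal(d2$values, c(0, 1, 1, 0))
  # drop rule discards it entirely
  d3 <- density_from_positions_1d(cells_1d(1), mesh, node_rule = "drop")
  expect_equal(d3$values, c(0, 0, 0, 0))
  expect_error(density_from_positions_1d(cells_1d(2.5), mesh),
               class = "woundfem_out_of_domain")
})

test_that("counting conserves total weight, under reordering and refinement", {
  set.seed(42)
  pos <- runif(37, 0.2, 6.8)
  for (ne in c(35L, 70L, 140L)) {
    mesh <- mesh_1d(7, ne)
    d <- density_from_positions_1d(cells_1d(pos), mesh)
    expect_equal(sum(mesh$h * d$values), 37)
    d_perm <- density_from_positions_1d(cells_1d(sample(pos)), mesh)
    expect_equal(d$values, d_perm$values)
  }
})

test_that("1D density-to-positions reproduces per-bin integral counts", {
  cfg <- positions_from_density_1d(function(x) rep(4, length(x)), L = 1,
                                   d = 0.5)
  expect_equal(nrow(cfg), 4L)
  expect_equal(cfg$x, c(0.125, 0.375, 0.625, 0.875))
  # sine density: per-bin counts against an adaptive-quadrature oracle
  nc <- function(x) 40 * abs(sin(2 * x))
  cfg2 <- positions_from_density_1d(nc, L = 7, d = 0.35)
  breaks <- seq(0, 7, by = 0.35)
  oracle <- sum(vapply(seq_len(20L), function(k) {
    v <- stats::integrate(nc, breaks[k], breaks[k + 1L],
                          rel.tol = 1e-10)$value
    sign(v) * floor(abs(v) + 0.5)
  }, numeric(1)))
  expect_equal(nrow(cfg2), oracle)
  # narrow Gaussian with total mass 50
  ncg <- function(x) 50 * stats::dnorm(x, 3.5, 0.1)
  cfg3 <- positions_from_density_1d(ncg, L = 7, d = 0.35)
  expect_equal(nrow(cfg3), 50L, tolerance = 1)
  expect_error(
    positions_from_density_1d(function(x) -x, L = 1, d = 0.5),
    class = "woundfem_invalid_density")
})

test_that("2D counting distributes interior, edge and vertex cells correctly", {
  mesh <- structured_trimesh(c(0, 2, 0, 2), 2, 2)
  # three cells strictly inside one triangle of area 0.5
  inside <- cells_2d(cbind(c(0.6, 0.7, 0.8), c(0.2, 0.25, 0.2)))
  d <- density_from_positions_2d(inside, mesh)
  expect_equal(sum(tidy(d)$count), 3)
  expect_equal(max(d$values), 3 / 0.5)
  # cell on the diagonal edge shared by two triangles
  edge <- cells_2d(cbind(0.25, 0.25))
  de <- density_from_positions_2d(edge, mesh)
  expect_equal(sort(unique(round(de$values * 0.5, 12))), c(0, 0.5))
  expect_equal(sum(tidy(de)$count), 1)
  # cell at the interior vertex (1, 1): incident angles sum to 2 pi
  vert <- cells_2d(cbind(1, 1))
  dv <- density_from_positions_2d(vert, mesh)
  expect_equal(sum(tidy(dv)$count), 1, tolerance = 1e-12)
  expect_error(density_from_positions_2d(cells_2d(cbind(3, 1)), mesh),
               class = "woundfem_out_of_domain")
})

test_that("random 2D cells are reproducible, separated and inside", {
  c1 <- random_cells_2d(c(-5, 5, -5, 5), 196, min_sep = 0.2, seed = 11)
  c2 <- random_cells_2d(c(-5, 5, -5, 5), 196, min_sep = 0.2, seed = 11)
  expect_identical(c1$x, c2$x)
  expect_identical(c1$y, c2$y)
  expect_equal(nrow(c1), 196L)
  expect_true(all(abs(c1$x) < 5 & abs(c1$y) < 5))
  dmin <- min(stats::dist(cbind(c1$x, c1$y)))
  expect_gte(dmin, 0.2)
  empty <- random_cells_2d(c(0, 1, 0, 1), 0)
  expect_equal(nrow(empty), 0L)
  expect_error(random_cells_2d(c(0, 1, 0, 1), 500, min_sep = 0.2),
               class = "woundfem_infeasible_packing")
})

test_that("2D density-to-positions counts integrals per tile", {
  cfg <- positions_from_density_2d(function(p) rep(4, nrow(p)),
                                   c(0, 2, 0, 2), cell_side = 1, seed = 3)
  expect_equal(nrow(cfg), 16L)
  ncg <- function(p) 50 / (2 * pi) * exp(-(p[, 1L]^2 + p[, 2L]^2) / 2)
  cfg2 <- positions_from_density_2d(ncg, c(-10, 10, -10, 10), seed = 5)
  expect_equal(nrow(cfg2), 50L, tolerance = 2)
  zero <- positions_from_density_2d(function(p) rep(0, nrow(p)),
                                    c(0, 2, 0, 2))
  expect_equal(nrow(zero), 0L)
})

test_that("position-density round trip conserves the total cell weight", {
  nc <- function(x) 40 * abs(sin(2 * x))
  cfg <- positions_from_density_1d(nc, L = 7, d = 0.35)
  for (ne in c(50L, 100L)) {
    mesh <- mesh_1d(7, ne)
    d <- density_from_positions_1d(cfg, mesh)
    expect_equal(sum(mesh$h * d$values), nrow(cfg))
  }
})
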