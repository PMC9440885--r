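test_that("L2 norm integrates the P1 interpolant exactly", {
  mesh <- mesh_1d(1, 10L)
  zero <- displacement_field_1d(mesh, numeric(11L))
  expect_equal(l2_norm(zero), 0)
  hat <- displacement_field_1d(mesh, c(rep(0, 5L), 1, rep(0, 5L)))
  expect_equal(l2_norm(hat), sqrt(2 * 0.1 / 3), tolerance = 1e-14)
  # interpolants of the piecewise-linear limit profile: exact closed form
  P <- 0.01 * 50 / 3
  fine <- mesh_1d(7, 700L)
  # wound edges 2 and 5 are nodes of this mesh, so the interpolant is exact
  interp <- displacement_field_1d(
    fine, limit_solution_1d(fine$nodes, P, 2, 5, 7))
  oracle <- sqrt(stats::integrate(
    function(x) limit_solution_1d(x, P, 2, 5, 7)^2, 0, 7,
    subdivisions = 1000L, rel.tol = 1e-12)$value)
  expect_equal(l2_norm(interp), oracle, tolerance = 1e-10)
  expect_equal(l2_norm(interp), 0.21822, tolerance = 1e-4)
})

test_that("L2 norm of smooth-function interpolants converges at second order", {
  f <- function(x) sin(pi * x / 7) * (7 - x) * x / 10
  exact <- sqrt(stats::integrate(function(x) f(x)^2, 0, 7,
                                 rel.tol = 1e-12)$value)
  errs <- vapply(c(20L, 40L, 80L), function(ne) {
    m <- mesh_1d(7, ne)
    abs(l2_norm(displacement_field_1d(m, f(m$nodes))) - exact)
  }, numeric(1))
  rates <- log2(errs[-3L] / errs[-1L])
  expect_true(all(rates > 1.8 & rates < 2.2))
})

test_that("H1 norm dominates L2 and gives exact seminorms for ramps", {
  mesh <- mesh_1d(1, 10L)
  ramp <- displacement_field_1d(mesh, mesh$nodes)  # u = x (test profile)
  expect_equal(h1_seminorm(ramp), 1, tolerance = 1e-12)
  hat <- displacement_field_1d(mesh, c(rep(0, 5L), 1, rep(0, 5L)))
  expect_gte(h1_norm(hat), l2_norm(hat))
  zero <- displacement_field_1d(mesh, numeric(11L))
  expect_equal(h1_norm(zero), 0)
})

test_that("RMS error measures nodal differences", {
  mesh <- mesh_1d(7, 70L)
  u2 <- function(x) continuum_solution_1d(x, 0.01, 2, 5, 7)
  f <- displacement_field_1d(mesh, u2(mesh$nodes))
  expect_equal(rms_error(f, u2), 0)
  g <- displacement_field_1d(mesh, u2(mesh$nodes) + 0.003)
  expect_equal(rms_error(g, u2), 0.003, tolerance = 1e-14)
})

test_that("convergence rate recovers synthetic and interpolation orders", {
  mesh <- mesh_1d(1, 16L)
  base <- sin(pi * mesh$nodes)
  bump <- mesh$nodes * (1 - mesh$nodes)
  mk <- function(v) displacement_field_1d(mesh, v)
  # second-order synthetic sequence: differences shrink by 4 per level
  r2 <- convergence_rate(list(mk(base + 4 * bump), mk(base + bump),
                              mk(base + 0 * bump)))
  expect_equal(r2$rate, log2((4 - 1) / 1), tolerance = 1e-12)
  r1 <- convergence_rate(list(mk(base + 3 * bump), mk(base + bump),
                              mk(base)))
  expect_equal(r1$rate, 1, tolerance = 1e-12)
  # interpolants of sin(pi x / L) on nested meshes: close to second order
  f <- function(x) sin(pi * x / 7)
  fields <- lapply(c(25L, 50L, 100L), function(ne) {
    m <- mesh_1d(7, ne)
    displacement_field_1d(m, f(m$nodes))
  })
  expect_equal(convergence_rate(fields)$rate, 2, tolerance = 0.1)
  same <- mk(base)
  expect_error(convergence_rate(list(same, same, same)),
               class = "woundfem_undefined_rate")
})

test_that("1D reduction ratio matches the analytic continuum value", {
  mesh <- mesh_1d(7, 700L)   # nodes at the wound edges
  zero <- displacement_field_1d(mesh, numeric(701L))
  r0 <- reduction_ratio_1d(zero, 2, 5)
  expect_equal(r0$reduction_percent, 0)
  expect_equal(r0$relative_percent, 100)
  u2 <- displacement_field_1d(
    mesh, continuum_solution_1d(mesh$nodes, 0.01, 2, 5, 7, scale = 50 / 3))
  r <- reduction_ratio_1d(u2, 2, 5)
  expect_equal(r$reduction_percent, 100 * (2 / 7) * (0.01 * 50 / 3) * 2 / 3 * 3,
               tolerance = 1e-10)
  expect_equal(r$reduction_percent, 9.5238, tolerance = 1e-4)
  expect_equal(r$reduction_percent + r$relative_percent, 100)
  dbl <- displacement_field_1d(mesh, 2 * u2$values)
  expect_equal(reduction_ratio_1d(dbl, 2, 5)$reduction_percent,
               2 * r$reduction_percent, tolerance = 1e-12)
})

test_that("2D area reduction uses shoelace areas", {
  poly <- rect_polyline(c(0, 1, 0, 1), 25)
  expect_equal(polygon_area(poly), 1, tolerance = 1e-12)
  r0 <- area_reduction_2d(poly, poly)
  expect_equal(r0$reduction_percent, 0)
  shrunk <- poly
  shrunk[, 1L] <- 0.5 + 0.9 * (poly[, 1L] - 0.5)
  r <- area_reduction_2d(poly, shrunk)
  expect_equal(r$reduction_percent, 10, tolerance = 1e-10)
  both <- cbind(0.5 + 0.9 * (poly[, 1L] - 0.5), 0.5 + 0.9 * (poly[, 2L] - 0.5))
  expect_equal(area_reduction_2d(poly, both)$reduction_percent, 19,
               tolerance = 1e-10)
  expect_equal(r$reduction_percent + r$relative_percent, 100)
})

test_that("consistency gap is zero for identical fields and checks meshes", {
  mesh <- mesh_1d(7, 70L)
  u <- displacement_field_1d(mesh, sin(mesh$nodes) * 0.01)
  g <- consistency_gap(u, u)
  expect_equal(g$l2, 0)
  expect_equal(g$sup, 0)
  expect_equal(g$h1, 0)
  other <- displacement_field_1d(mesh_1d(7, 35L), numeric(36L))
  expect_error(consistency_gap(u, other),
               class = "woundfem_incompatible_mesh")
})
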