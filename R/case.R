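#' Case configuration
#'
#' Bundles everything needed to run a contraction simulation: geometry,
#' material, force magnitude, cell source, numerical controls and seed.
#' Unspecified values default to the standard 1D benchmark (domain `(0, 7)`,
#' wound `(2, 5)`, `P = 0.01`, `E = 1`) or, for `dim = 2`, to the standard
#' 2D benchmark (domain `(-10, 10)^2`, wound `(-5, 5)^2`, `P = 10`,
#' `nu = 0.49`).
#'
#' @param dim Dimensionality, 1 or 2.
#' @param cells Cell source: a list with `source` one of `"uniform"` (1D;
#'   fields `n`), `"density"` (fields `nc`, a density function, and bin
#'   length `d` / `cell_side`), `"positions"` (field `positions`), or
#'   `"random"` (2D; fields `n`, `min_sep`).
#' @param L,a,b 1D geometry: domain length and wound endpoints.
#' @param domain,wound 2D geometry: outer and wound rectangles
#'   `c(xmin, xmax, ymin, ymax)`.
#' @param E,nu Material stiffness and (2D) Poisson ratio.
#' @param P Force magnitude.
#' @param forcing `"both"` (default), `"sp"` or `"density"`.
#' @param n_elem 1D element count; `nx`, `ny` 2D squares per direction.
#' @param nx,ny 2D grid resolution.
#' @param eps_factor Mollifier width is `h / eps_factor` (default 3).
#' @param node_rule Counting rule for node-coincident cells, see
#'   [density_from_positions_1d()].
#' @param samples_per_edge Wound-boundary samples per edge (2D metrics).
#' @param seed Master seed for all randomness in the case.
#' @return A `case_config` list.
#' @export
case_config <- function(dim = 1,
                        cells = list(source = "uniform", n = 50),
                        L = 7, a = 2, b = 5,
                        domain = c(-10, 10, -10, 10),
                        wound = c(-5, 5, -5, 5),
                        E = 1, nu = 0.49,
                        P = if (dim == 1) 0.01 else 10,
                        forcing = c("both", "sp", "density"),
                        n_elem = 100, nx = 40, ny = 40,
                        eps_factor = 3,
                        node_rule = c("half", "drop"),
                        samples_per_edge = 50,
                        seed = 1L) {
  structure(list(dim = dim, cells = cells, L = L, a = a, b = b,
                 domain = domain, wound = wound, E = E, nu = nu, P = P,
                 forcing = match.arg(forcing), n_elem = n_elem,
                 nx = nx, ny = ny, eps_factor = eps_factor,
                 node_rule = match.arg(node_rule),
                 samples_per_edge = samples_per_edge,
                 seed = as.integer(seed)),
            class = "case_config")
}

build_cells <- function(config) {
  src <- config$cells$source
  P <- config$P
  if (config$dim == 1) {
    switch(src,
      uniform = uniform_cells_1d(config$a, config$b, config$cells$n, P = P),
      density = positions_from_density_1d(
        config$cells$nc, config$L, config$cells$d, P = P,
        placement = config$cells$placement %||% "equispaced",
        seed = config$seed),
      positions = cells_1d(config$cells$positions, P = P),
      abort(sprintf("Unknown 1D cell source '%s'.", src)))
  } else {
    switch(src,
      random = random_cells_2d(config$wound, config$cells$n,
                               min_sep = config$cells$min_sep %||% 0.2,
                               seed = config$seed, P = P),
      density = positions_from_density_2d(
        config$cells$nc, config$domain,
        cell_side = config$cells$cell_side %||% 1,
        seed = config$seed, P = P),
      positions = cells_2d(config$cells$positions, P = P),
      abort(sprintf("Unknown 2D cell source '%s'.", src)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a contraction case
#'
#' Executes the full pipeline selected by the configuration: generate or
#' accept cells, build the piecewise-constant density (agent-to-continuum
#' upscaling), assemble the smoothed-particle and/or cell-density loads,
#' solve, and compute the standard diagnostics (L2 and H1 norms, reduction
#' ratio of the wound, consistency gap when both models run).
#'
#' In 1D the stiffness `E` enters by scaling the force as `P / E` (the
#' Poisson problem is solved with unit stiffness); in 2D `E` and `nu` enter
#' the plane-strain constitutive law.
#'
#' @param config A [case_config()].
#' @return A `woundfem_case` object: list with `config`, `cells`, `mesh`,
#'   `density`, `epsilon`, `fields` (named list of displacement fields),
#'   `metrics` (tibble, one row per model), `gap` (or `NULL`) and, in 2D,
#'   the original and deformed wound boundary polygons.
#' @examples
#' res <- run_case(case_config(dim = 1, cells = list(source = "uniform", n = 50)))
#' glance(res)
#' @export
run_case <- function(config) {
  stopifnot(inherits(config, "case_config"))
  cells <- build_cells(config)
  if (config$dim == 1) run_case_1d(config, cells) else run_case_2d(config, cells)
}

run_case_1d <- function(config, cells) {
  mesh <- mesh_1d(config$L, config$n_elem)
  eps <- mesh$h / config$eps_factor
  Peff <- config$P / config$E
  cells_eff <- cells
  attr(cells_eff, "P") <- Peff
  density <- density_from_positions_1d(cells, mesh, node_rule = config$node_rule)
  fields <- list()
  if (config$forcing %in% c("both", "sp")) {
    fields$sp <- solve_1d(mesh, load_sp_1d(mesh, cells_eff, eps))
  }
  if (config$forcing %in% c("both", "density")) {
    fields$density <- solve_1d(mesh, load_density_1d(mesh, density, Peff))
  }
  metrics <- purrr::imap_dfr(fields, function(f, nm) {
    red <- reduction_ratio_1d(f, config$a, config$b)
    tibble(model = nm, l2 = l2_norm(f), h1 = h1_norm(f),
           reduction_percent = red$reduction_percent,
           relative_percent = red$relative_percent)
  })
  gap <- if (length(fields) == 2L) consistency_gap(fields$sp, fields$density)
  structure(list(config = config, cells = cells, mesh = mesh,
                 density = density, epsilon = eps, fields = fields,
                 metrics = metrics, gap = gap),
            class = "woundfem_case")
}

run_case_2d <- function(config, cells) {
  mesh <- structured_trimesh(config$domain, config$nx, config$ny)
  eps <- min(attr(mesh, "dx"), attr(mesh, "dy")) / config$eps_factor
  mat <- elastic_params(config$E, config$nu)
  density <- density_from_positions_2d(cells, mesh)
  fields <- list()
  if (config$forcing %in% c("both", "sp")) {
    fields$sp <- solve_2d(mesh, mat, load_sp_2d(mesh, cells, eps))
  }
  if (config$forcing %in% c("both", "density")) {
    fields$density <- solve_2d(mesh, mat,
                               load_density_2d(mesh, density, config$P))
  }
  poly <- rect_polyline(config$wound, config$samples_per_edge)
  boundaries <- purrr::map(fields, deformed_boundary, polyline = poly)
  metrics <- purrr::imap_dfr(fields, function(f, nm) {
    red <- area_reduction_2d(poly, boundaries[[nm]])
    tibble(model = nm, l2 = l2_norm(f), h1 = h1_norm(f),
           reduction_percent = red$reduction_percent,
           relative_percent = red$relative_percent)
  })
  gap <- if (length(fields) == 2L) consistency_gap(fields$sp, fields$density)
  structure(list(config = config, cells = cells, mesh = mesh,
                 density = density, epsilon = eps, fields = fields,
                 metrics = metrics, gap = gap,
                 wound_polygon = poly, deformed_polygons = boundaries),
            class = "woundfem_case")
}

#' @export
print.woundfem_case <- function(x, ...) {
  cat(sprintf("<woundfem_case> dim %d, %d cells, %s forcing\n",
              x$config$dim, nrow(x$cells), x$config$forcing))
  print(x$metrics)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.woundfem_case <- function(x, ...) {
  wide <- metrics_wide(x$metrics)
  extra <- tibble(dim = x$config$dim, n_cells = nrow(x$cells),
                  epsilon = x$epsilon, seed = x$config$seed)
  out <- dplyr::bind_cols(extra, wide)
  if (!is.null(x$gap)) {
    out$gap_l2 <- x$gap$l2; out$gap_sup <- x$gap$sup; out$gap_h1 <- x$gap$h1
  }
  out
}

# one-row wide form of the per-model metrics table
metrics_wide <- function(metrics) {
  pieces <- lapply(seq_len(nrow(metrics)), function(i) {
    row <- metrics[i, -1L]
    names(row) <- paste(metrics$model[i], names(row), sep = "_")
    row
  })
  dplyr::bind_cols(pieces)
}

#' @exportS3Method generics::tidy
tidy.woundfem_case <- function(x, ...) {
  purrr::imap_dfr(x$fields, function(f, nm) {
    dplyr::mutate(tidy(f), model = nm, .before = 1L)
  })
}

#' Nested mesh-refinement sweep
#'
#' Reruns a case on `levels` nested meshes (each halving `h`, starting from
#' the configured resolution) with the cells held fixed and the mollifier
#' width rescaled as `h_level / eps_factor`, then estimates the
#' L2-convergence rate from differences of nested solutions for each force
#' model.
#'
#' @param config A [case_config()].
#' @param levels Number of refinement levels (`>= 3`).
#' @return A `woundfem_sweep`: list with `norms` (tibble: level, h, model,
#'   l2, h1) and `rates` (tibble: model, rate and the two difference norms).
#' @export
converge_sweep <- function(config, levels = 3L) {
  stopifnot(inherits(config, "case_config"), levels >= 3L)
  cells <- build_cells(config)
  cases <- vector("list", levels)
  for (lev in seq_len(levels)) {
    cfg <- config
    if (config$dim == 1) {
      cfg$n_elem <- config$n_elem * 2L^(lev - 1L)
    } else {
      cfg$nx <- config$nx * 2L^(lev - 1L)
      cfg$ny <- config$ny * 2L^(lev - 1L)
    }
    cases[[lev]] <- if (config$dim == 1) run_case_1d(cfg, cells)
                    else run_case_2d(cfg, cells)
  }
  norms <- purrr::imap_dfr(cases, function(cs, lev) {
    h <- if (config$dim == 1) cs$mesh$h else attr(cs$mesh, "dx")
    dplyr::mutate(cs$metrics[, c("model", "l2", "h1")],
                  level = lev, h = h, .before = 1L)
  })
  models <- names(cases[[1L]]$fields)
  rates <- purrr::map_dfr(models, function(nm) {
    r <- convergence_rate(lapply(cases[(levels - 2L):levels],
                                 function(cs) cs$fields[[nm]]))
    # rate from differences of the per-level norms, the convention used in
    # tabulated benchmarks; meaningful when the norms approach their limit
    # monotonically
    n3 <- vapply(cases[(levels - 2L):levels],
                 function(cs) l2_norm(cs$fields[[nm]]), numeric(1))
    rate_norms <- if ((n3[3L] - n3[2L]) != 0 &&
                      (n3[2L] - n3[1L]) / (n3[3L] - n3[2L]) > 0) {
      log2((n3[2L] - n3[1L]) / (n3[3L] - n3[2L]))
    } else NA_real_
    tibble(model = nm, rate = r$rate, rate_norms = rate_norms,
           d1 = r$d1, d2 = r$d2)
  })
  structure(list(norms = norms, rates = rates, cases = cases),
            class = "woundfem_sweep")
}

#' @export
print.woundfem_sweep <- function(x, ...) {
  cat("<woundfem_sweep>\n")
  print(x$norms); print(x$rates)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.woundfem_sweep <- function(x, ...) x$norms

#' @exportS3Method generics::glance
glance.woundfem_sweep <- function(x, ...) {
  out <- lapply(seq_len(nrow(x$rates)), function(i) {
    tibble(rate = x$rates$rate[i])
  })
  names(out) <- x$rates$model
  res <- dplyr::bind_cols(tibble(levels = length(x$cases)),
                          purrr::imap_dfc(out, function(v, nm) {
                            names(v) <- paste0(nm, "_rate"); v
                          }))
  res
}
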