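#' Read and write cell positions as CSV
#'
#' Positions are stored with header `x` (1D) or `x,y` (2D), one row per
#' cell, full double precision; the force magnitude is not stored and is
#' supplied on reading.
#'
#' @param cells A [cells_1d()] or [cells_2d()] configuration.
#' @param path File path.
#' @return `write_positions_csv()` returns `path` invisibly;
#'   `read_positions_csv()` returns a cell configuration.
#' @export
write_positions_csv <- function(cells, path) {
  df <- as.data.frame(lapply(as.data.frame(cells), format_full))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_positions_csv
#' @param P Force magnitude to attach to the configuration read.
#' @export
read_positions_csv <- function(path, P = 1) {
  df <- utils::read.csv(path)
  if (ncol(df) == 1L) cells_1d(df[[1L]], P = P) else cells_2d(df, P = P)
}

format_full <- function(x) sprintf("%.17g", x)

#' Read and write 1D solutions as CSV
#'
#' Nodal solutions use header `x,u`; values are written with 17 significant
#' digits so a round trip reproduces them exactly.
#'
#' @param field A `displacement_field_1d`.
#' @param path File path.
#' @export
write_solution_csv <- function(field, path) {
  stopifnot(inherits(field, "displacement_field_1d"))
  df <- data.frame(x = format_full(field$mesh$nodes),
                   u = format_full(field$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_solution_csv
#' @export
read_solution_csv <- function(path) {
  df <- utils::read.csv(path)
  as_tibble(df)
}

#' Write a polyline as CSV
#'
#' Ordered `x,y` samples of a (closed) wound boundary.
#'
#' @param poly `n x 2` matrix.
#' @param path File path.
#' @export
write_polyline_csv <- function(poly, path) {
  df <- data.frame(x = format_full(poly[, 1L]), y = format_full(poly[, 2L]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a 2D solution as a legacy VTK unstructured grid
#'
#' ASCII VTK with the mesh triangles, a point vector field `displacement`
#' and, optionally, a cell scalar `cell_density` -- loadable by ParaView
#' and standard VTK readers.
#'
#' @param field A `displacement_field_2d`.
#' @param path File path (conventionally `.vtk`).
#' @param density Optional [density_field_2d()] on the same mesh.
#' @export
write_vtk <- function(field, path, density = NULL) {
  stopifnot(inherits(field, "displacement_field_2d"))
  mesh <- field$mesh
  np <- nrow(mesh$nodes); nt <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "woundfem displacement field", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", np)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  writeLines(sprintf("CELLS %d %d", nt, 4L * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1L] - 1L,
                     mesh$triangles[, 2L] - 1L, mesh$triangles[, 3L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("5", nt), con)
  writeLines(c(sprintf("POINT_DATA %d", np),
               "VECTORS displacement double"), con)
  writeLines(sprintf("%.17g %.17g 0", field$values[, 1L], field$values[, 2L]),
             con)
  if (!is.null(density)) {
    writeLines(c(sprintf("CELL_DATA %d", nt),
                 "SCALARS cell_density double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", density$values), con)
  }
  invisible(path)
}

#' Read back a VTK file written by [write_vtk()]
#'
#' Minimal reader for round-trip checks: returns the points, triangles and
#' the `displacement` vectors.
#'
#' @param path File path.
#' @return List with `nodes`, `triangles`, `displacement`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  np <- as.integer(strsplit(lines[ip], " ")[[1L]][2L])
  pts <- do.call(rbind, lapply(strsplit(lines[ip + seq_len(np)], " "),
                               function(v) as.numeric(v[1:2])))
  ic <- grep("^CELLS", lines)
  nt <- as.integer(strsplit(lines[ic], " ")[[1L]][2L])
  tri <- do.call(rbind, lapply(strsplit(lines[ic + seq_len(nt)], " "),
                               function(v) as.integer(v[2:4]) + 1L))
  iv <- grep("^VECTORS displacement", lines)
  disp <- do.call(rbind, lapply(strsplit(lines[iv + seq_len(np)], " "),
                                function(v) as.numeric(v[1:2])))
  list(nodes = pts, triangles = tri, displacement = disp)
}

#' Write a JSON case report
#'
#' Self-describing record of a run: configuration echo (including the
#' counting and placement rules in effect), seed, per-model norms and
#' reduction ratios, consistency gap, all at full precision.
#'
#' @param case A `woundfem_case` from [run_case()].
#' @param path File path.
#' @export
write_report_json <- function(case, path) {
  cfg <- case$config
  report <- list(
    parameters = cfg[setdiff(names(cfg), "cells")],
    cell_source = cfg$cells$source,
    n_cells = nrow(case$cells),
    epsilon = case$epsilon,
    seed = cfg$seed,
    metrics = case$metrics,
    gap = case$gap)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE, pretty = TRUE)
  invisible(path)
}
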