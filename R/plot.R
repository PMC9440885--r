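#' Plot a 1D displacement field
#'
#' Line plot of the piecewise-linear solution, optionally with cell centre
#' positions along the axis.
#'
#' @param object A `displacement_field_1d`.
#' @param cells Optional [cells_1d()] to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.displacement_field_1d <- function(object, cells = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$x, y = .data$u)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "x", y = "displacement u(x)") +
    ggplot2::theme_minimal()
  if (!is.null(cells)) {
    p <- p + ggplot2::geom_point(
      data = tibble(x = cells$x, u = 0),
      colour = "steelblue", size = 0.8)
  }
  p
}

#' Plot a 2D displacement magnitude field
#'
#' Nodal displacement magnitude on the structured grid.
#'
#' @param object A `displacement_field_2d`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.displacement_field_2d <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "|u|") +
    ggplot2::theme_minimal()
}

#' Plot a case result
#'
#' 1D cases: both model solutions overlaid. 2D cases: the wound boundary
#' before (red) and after (black) deformation, with cell centres in blue --
#' the standard contraction picture.
#'
#' @param object A `woundfem_case`.
#' @param model Which model's boundary to draw in 2D (default first).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.woundfem_case <- function(object, model = NULL, ...) {
  if (object$config$dim == 1) {
    df <- tidy(object)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$u,
                                       colour = .data$model)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "x", y = "u(x)", colour = NULL) +
        ggplot2::theme_minimal())
  }
  model <- model %||% names(object$fields)[1L]
  closed <- function(m) as.data.frame(rbind(m, m[1L, , drop = FALSE])) |>
    stats::setNames(c("x", "y"))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = closed(object$wound_polygon),
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "red") +
    ggplot2::geom_path(data = closed(object$deformed_polygons[[model]]),
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "black") +
    ggplot2::geom_point(data = as.data.frame(object$cells),
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "steelblue", size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Wound contraction (%s model)", model)) +
    ggplot2::theme_minimal()
}
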