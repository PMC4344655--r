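#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster grid
#'
#' @param grid A [raster_grid()].
#' @return A ggplot tile map (invalid cells blank).
#' @export
plot_grid_field <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  df <- tidyr::expand_grid(lat = grid_lats(grid$geo), lon = grid_lons(grid$geo))
  df$value <- as.vector(t(grid$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      na.value = "grey20",
      name = if (is.na(grid$units)) "value" else grid$units
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = grid$varname, x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Silhouette profile of a topology scan
#'
#' Mean silhouette index against cluster count, one point per lattice
#' topology; the selected scenario is highlighted.
#'
#' @param object A `som_scan` from [run_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.som_scan <- function(object, ...) {
  df <- tidy.som_scan(object)
  df$topology <- sprintf("%d x %d", df$x, df$y)
  best <- select_best(object)
  ggplot2::ggplot(df[!df$flagged, ],
                  ggplot2::aes(.data$k, .data$mean_si)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$x == 1), size = 2) +
    ggplot2::geom_point(data = df[df$k == best$k & df$x == best$x, ],
                        color = "red", size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 17, `FALSE` = 16),
                                name = "linear topology") +
    ggplot2::labs(x = "number of clusters (X x Y)",
                  y = "mean silhouette index") +
    ggplot2::theme_minimal()
}

#' Class map of a pipeline run
#'
#' @param run A `seascape_run` (or pass `labels` + `table` explicitly).
#' @return A ggplot tile map of class labels over the grid.
#' @export
plot_class_map <- function(run) {
  stopifnot(inherits(run, "seascape_run"))
  df <- run$table_raw
  df$class <- factor(run$best$labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "class") +
    ggplot2::theme_minimal()
}

#' Neuron diagnostics of a trained SOM
#'
#' Lattice layout with edges shaded by the feature-space distance between
#' adjacent neurons (the unified-distance view): dark edges separate
#' dissimilar classes.
#'
#' @param object A `som_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.som_model <- function(object, ...) {
  pos <- object$lattice$positions
  nd <- neighbor_weight_distances(object)
  seg <- tibble::tibble(
    x = pos[nd$i, 1], y = pos[nd$i, 2],
    xend = pos[nd$j, 1], yend = pos[nd$j, 2],
    distance = nd$distance
  )
  nodes <- tibble::tibble(x = pos[, 1], y = pos[, 2],
                          neuron = seq_len(object$lattice$k))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(.data$x, .data$y, xend = .data$xend, yend = .data$yend,
                   color = .data$distance),
      linewidth = 2
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 6, shape = 21, fill = "steelblue") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$neuron),
                       color = "white", size = 3) +
    ggplot2::scale_color_gradient(low = "grey85", high = "black") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Weight planes of a trained SOM
#'
#' One panel per input variable showing each neuron's weight on the lattice
#' layout — how each biophysical variable contributes to each class.
#'
#' @param model A `som_model`.
#' @return A ggplot.
#' @export
plot_weight_planes <- function(model) {
  df <- input_weight_planes(model)
  ggplot2::ggplot(df, ggplot2::aes(.data$px, .data$py,
                                   color = .data$weight)) +
    ggplot2::geom_point(size = 5) +
    ggplot2::facet_wrap(~variable) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
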