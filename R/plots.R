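# ggplot2 displays for the main result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# equal-area-ish longitude/latitude projection of sphere vertices
project_mesh <- function(mesh, vertices = seq_len(nrow(mesh$coords))) {
  xyz <- mesh$coords[vertices, , drop = FALSE]
  r <- sqrt(rowSums(xyz^2))
  tibble::tibble(
    vertex = vertices,
    lon = atan2(xyz[, 2], xyz[, 1]),
    lat = asin(pmin(1, pmax(-1, xyz[, 3] / r)))
  )
}

#' Plot a parcellation on the flattened mesh
#'
#' @param object an `fc_parcellation`.
#' @param mesh the [surface_mesh()] the parcellation lives on.
#' @param ... unused.
#' @return A ggplot object: ROI vertices in longitude/latitude, colored by
#'   network.
#' @export
autoplot.fc_parcellation <- function(object, mesh, ...) {
  df <- dplyr::left_join(tidy(object), project_mesh(mesh, object$roi_vertices),
                         by = "vertex")
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   color = factor(.data$network))) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_fixed() +
    ggplot2::labs(color = "network", x = "longitude", y = "latitude",
                  title = sprintf("%s parcellation, %d networks",
                                  object$level, object$k)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fc_parcellation
#' @export
autoplot.fc_metric <- function(object, ...) {
  ggplot2::ggplot(object$per_network,
                  ggplot2::aes(factor(.data$network), .data$value)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$summary_value, linetype = 2) +
    ggplot2::labs(x = "network", y = object$metric_name,
                  title = sprintf("%s (summary %.4f)", object$metric_name,
                                  object$summary_value)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fc_parcellation
#' @export
autoplot.fc_individual <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$iteration, .data$dice_vs_previous)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "Dice vs previous iteration",
                  title = "Individualization convergence") +
    ggplot2::theme_minimal()
}

#' Model-order selection curve
#'
#' @param table output of [model_order_table()].
#' @return A ggplot of the Dice x silhouette product over K, with selected
#'   local maxima highlighted.
#' @export
plot_model_order <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(.data$k, .data$product)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$selected), size = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(y = "Dice x silhouette", color = "selected") +
    ggplot2::theme_minimal()
}
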