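# Distance-map colour convention: red marks minimal intraarticular
# distance (closest contact), blue marks maximal distance.
dm_palette <- function() c("red", "orange", "yellow", "green", "blue")

#' Plot a projected distance map
#'
#' Axial heatmap of the projected talar dome: warm colours mark close
#' contact, cold colours large intraarticular distance; cyst samples are
#' drawn as hollow points (holes in the map).
#'
#' @param object A [project_axial()] result.
#' @param point_size Point size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bst_projected_map <- function(object, point_size = 0.8, ...) {
  valid <- object[object$flag == "valid", ]
  cyst <- object[object$flag == "cyst", ]
  p <- ggplot2::ggplot(valid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$distance), size = point_size) +
    ggplot2::scale_colour_gradientn(colours = dm_palette(),
                                    name = "distance (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, + = lateral)", y = "y (mm, + = anterior)",
                  title = "Talar dome distance map (axial view)") +
    ggplot2::theme_minimal()
  if (nrow(cyst) > 0L) {
    p <- p + ggplot2::geom_point(data = cyst, shape = 1, size = point_size,
                                 colour = "grey40")
  }
  p
}

#' Plot a Battleship-technique result
#'
#' The 16-square grid shaded by distance-mapping coefficient (red = close
#' contact / high DMC, blue = far / low DMC) with quadrant labels and the
#' distance-map weighted-sum point.
#'
#' @param object A `bst_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bst_result <- function(object, ...) {
  sq <- object$squares
  ggplot2::ggplot(sq, ggplot2::aes(x = .data$cx, y = .data$cy)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$dmc),
                       width = 0.25, height = 0.25, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$quadrant),
                       size = 2.6, colour = "grey20") +
    ggplot2::scale_fill_gradientn(colours = rev(dm_palette()), name = "DMC",
                                  na.value = "grey90") +
    ggplot2::annotate("point", x = object$tws_x, y = object$tws_y,
                      shape = 21, size = 3, fill = "white", colour = "black") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "normalized x (+ = lateral)", y = "normalized y (+ = anterior)",
      title = sprintf("DMWS (%+.4f, %+.4f): %s / %s", object$tws_x,
                      object$tws_y, object$coronal_class, object$sagittal_class)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a reliability report
#'
#' Dot-and-interval plot of the ICC entries of a [reliability_report()].
#'
#' @param data A [reliability_report()] tibble.
#' @return A ggplot object.
#' @export
plot_reliability <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$estimate,
                                     y = paste(.data$type, .data$stratum),
                                     colour = .data$measure)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9), linetype = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "ICC(2,1)", y = NULL) +
    ggplot2::theme_minimal()
}
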