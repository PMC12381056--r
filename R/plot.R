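# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of per-patch fusion scores
#'
#' @param object an `od_scores` tibble from [score_patches()].
#' @param grid the matching [patch_grid()].
#' @param ... unused.
#' @return A ggplot object (10 x 10 tile map, winning patch outlined).
#' @export
autoplot.od_scores <- function(object, grid = patch_grid(), ...) {
  df <- dplyr::left_join(grid, object, by = "patch")
  win <- df[df$patch == attr(object, "patch_max"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = win, fill = NA, color = "red", linewidth = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "patch column", y = "patch row", fill = "L_i",
                  title = "Patch fusion scores")
}

#' Localization/segmentation overlay
#'
#' Draws the enhanced grayscale image with the detected center and, when
#' present, the segmented disc contour.
#'
#' @param object an `od_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.od_result <- function(object, ...) {
  g <- object$pre$gray_enhanced
  H <- nrow(g); W <- ncol(g)
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(grDevices::as.raster(g / 255),
                               xmin = 0.5, xmax = W + 0.5,
                               ymin = -(H + 0.5), ymax = -0.5) +
    ggplot2::annotate("point", x = object$center$x, y = -object$center$y,
                      color = "red", shape = 3, size = 4, stroke = 1.5) +
    ggplot2::coord_equal(xlim = c(0.5, W + 0.5), ylim = c(-(H + 0.5), -0.5),
                         expand = FALSE) +
    ggplot2::labs(x = "x", y = "y", title = "Optic disc localization")
  if (!is.null(object$mask)) {
    m <- object$mask$mask
    df <- data.frame(x = as.vector(col(m)), y = -as.vector(row(m)),
                     z = as.vector(m))
    p <- p + ggplot2::geom_contour(
      data = df, ggplot2::aes(x = .data$x, y = .data$y, z = .data$z),
      breaks = 0.5, color = "cyan", linewidth = 0.8)
  }
  p
}

#' Phantom with ground-truth overlays
#'
#' @param object a `phantom_truth` from [generate_phantom()].
#' @param ... unused.
#' @return A ggplot object (RGB phantom, disc contour, center mark).
#' @export
autoplot.phantom_truth <- function(object, ...) {
  px <- object$image$pixels
  H <- nrow(px); W <- ncol(px)
  rast <- grDevices::as.raster(px / 255)
  m <- object$disc_mask
  df <- data.frame(x = as.vector(col(m)), y = -as.vector(row(m)),
                   z = as.vector(m))
  ggplot2::ggplot() +
    ggplot2::annotation_raster(rast, xmin = 0.5, xmax = W + 0.5,
                               ymin = -(H + 0.5), ymax = -0.5) +
    ggplot2::geom_contour(data = df,
                          ggplot2::aes(x = .data$x, y = .data$y, z = .data$z),
                          breaks = 0.5, color = "white", linewidth = 0.6) +
    ggplot2::annotate("point", x = object$center[1], y = -object$center[2],
                      color = "white", shape = 3, size = 3) +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "x", y = "y", title = "Synthetic fundus phantom")
}
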