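#' Plot an RGB image, optionally with mask or superpixel overlays
#'
#' @param rgb_image H x W x 3 array on the 0-255 scale.
#' @param mask Optional logical matrix drawn as a contour-style overlay.
#' @param label_map Optional superpixel label matrix whose boundaries are
#'   drawn on top.
#' @return A ggplot object.
#' @export
plot_lesion_image <- function(rgb_image, mask = NULL, label_map = NULL) {
  assert_image(rgb_image)
  H <- dim(rgb_image)[1]
  W <- dim(rgb_image)[2]
  df <- tidyr::expand_grid(row = seq_len(H), col = seq_len(W))
  df$fill <- grDevices::rgb(clip01(rgb_image[, , 1]) / 255,
                            clip01(rgb_image[, , 2]) / 255,
                            clip01(rgb_image[, , 3]) / 255)[
    (df$col - 1L) * H + df$row]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(label_map)) {
    b <- label_boundaries(label_map)
    bd <- which(b, arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = data.frame(col = bd[, 2], row = bd[, 1]),
      ggplot2::aes(x = .data$col, y = .data$row),
      color = "yellow", size = 0.1)
  }
  if (!is.null(mask)) {
    e <- mask_edge(as_logical_mask(mask))
    ed <- which(e, arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = data.frame(col = ed[, 2], row = ed[, 1]),
      ggplot2::aes(x = .data$col, y = .data$row),
      color = "cyan", size = 0.2)
  }
  p
}

# Pixels whose label differs from the right or lower neighbour.
label_boundaries <- function(label_map) {
  H <- nrow(label_map)
  W <- ncol(label_map)
  b <- matrix(FALSE, H, W)
  b[, -W] <- b[, -W] | (label_map[, -W] != label_map[, -1])
  b[-H, ] <- b[-H, ] | (label_map[-H, ] != label_map[-1, ])
  b
}

mask_edge <- function(mask) {
  H <- nrow(mask)
  W <- ncol(mask)
  e <- matrix(FALSE, H, W)
  e[, -W] <- e[, -W] | (mask[, -W] != mask[, -1])
  e[-H, ] <- e[-H, ] | (mask[-H, ] != mask[-1, ])
  e & mask
}

#' Bar chart of per-model test metrics from a pipeline result
#'
#' @param object An `sp_pipeline_result` (or its `metrics` tibble).
#' @param ... Unused.
#' @return A ggplot object: one panel per metric, one bar per model.
#' @export
autoplot.sp_pipeline_result <- function(object, ...) {
  metrics <- if (inherits(object, "sp_pipeline_result")) object$metrics else object
  long <- tidyr::pivot_longer(
    metrics[, c("model", "accuracy", "precision", "recall", "f1", "mcc")],
    cols = -"model", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-model metrics of a pipeline result
#' @param x An `sp_pipeline_result`.
#' @param ... Unused.
#' @return The metrics tibble (one row per model).
#' @export
tidy.sp_pipeline_result <- function(x, ...) x$metrics

#' One-row summary of a pipeline run
#' @param x An `sp_pipeline_result`.
#' @param ... Unused.
#' @return Tibble with image/record counts, best model and best accuracy.
#' @export
glance.sp_pipeline_result <- function(x, ...) {
  best <- which.max(x$metrics$accuracy)
  tibble::tibble(n_images = length(x$masks),
                 n_records = nrow(x$features),
                 n_models = length(x$models),
                 best_model = x$metrics$model[best],
                 best_accuracy = x$metrics$accuracy[best],
                 seed = x$config$seed)
}
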