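# ggplot2 visualisations for the result types.

matrix_to_tibble <- function(m, max_px = 250000L) {
  step <- ceiling(sqrt(length(m) / max_px))
  ri <- seq(1, nrow(m), by = step)
  ci <- seq(1, ncol(m), by = step)
  sub <- m[ri, ci, drop = FALSE]
  tibble::tibble(row = rep(ri, times = length(ci)),
                 col = rep(ci, each = length(ri)),
                 value = as.vector(sub))
}

#' Plot a fluence map
#'
#' @param object a [fluence_map()].
#' @param max_px approximate maximum number of pixels drawn (larger maps are
#'   strided).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fluence_map <- function(object, max_px = 250000L, ...) {
  df <- matrix_to_tibble(map_pixels(object), max_px)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "dose [cGy]") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "in-plane [px]", y = "SI [px]") +
    ggplot2::theme_minimal()
}

#' Plot the five comparison maps of a baseline/error pair
#'
#' @param object a `comparison_maps` object.
#' @param maps which maps to draw.
#' @param max_px approximate maximum pixels per panel.
#' @param ... unused.
#' @return A faceted ggplot object.
#' @export
autoplot.comparison_maps <- function(object,
                                     maps = c("dd", "luminance", "contrast",
                                              "structure", "ssim"),
                                     max_px = 62500L, ...) {
  maps <- match.arg(maps, several.ok = TRUE)
  df <- dplyr::bind_rows(lapply(maps, function(nm) {
    dplyr::mutate(matrix_to_tibble(object[[nm]], max_px), map = nm)
  }))
  df$map <- factor(df$map, levels = maps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::facet_wrap(~map) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heatmap
#'
#' @param object a [confusion()] matrix.
#' @param normalize show row-normalised rates instead of counts.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, normalize = FALSE, ...) {
  m <- unclass(object)
  if (normalize) m <- m / pmax(rowSums(m), 1)
  df <- tibble::tibble(
    true = factor(rep(rownames(object), times = ncol(object)),
                  levels = rev(rownames(object))),
    predicted = factor(rep(colnames(object), each = nrow(object)),
                       levels = colnames(object)),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = if (normalize) sprintf("%.2f", .data$value)
              else .data$value), colour = "white") +
    ggplot2::scale_fill_viridis_c(name = if (normalize) "rate" else "count") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object the result of [roc_auc()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.epid_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Plot a CNN training-loss trace
#'
#' @param object a trained `cnn_model`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cnn_model <- function(object, ...) {
  stopifnot(object$trained)
  df <- tibble::tibble(epoch = seq_along(object$loss), loss = object$loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy") +
    ggplot2::theme_minimal()
}
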