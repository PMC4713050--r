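# ggplot2 views of the result objects.

#' Kernel-importance plot of an FSMKL fit
#'
#' Bars of the sorted kernel weights with the cumulative share, mirroring
#' the usual way sparse MKL solutions are reported.
#'
#' @param object An `fsmkl_fit`.
#' @param top Number of kernels to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fsmkl_fit <- function(object, top = 20, ...) {
  kern <- report_importance(object)$kernels
  kern <- kern[seq_len(min(top, nrow(kern))), ]
  lab <- sprintf("#%d %s k=%d %s", kern$rank, kern$group, kern$k, kern$family)
  kern$name <- factor(lab, levels = rev(lab))
  ggplot2::ggplot(kern, ggplot2::aes(x = .data$weight, y = .data$name)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "kernel weight", y = NULL,
                  title = "FSMKL kernel importance") +
    ggplot2::theme_minimal()
}

#' Mean ROC curves per model
#'
#' Vertical-averaged ROC curves of every model in a fold-results tibble.
#'
#' @param results A `fold_results` tibble from [evaluate_models()].
#' @return A ggplot.
#' @export
plot_mean_roc <- function(results) {
  curves <- results |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(curve = list(mean_roc(.data$roc)), .groups = "drop") |>
    tidyr::unnest("curve")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Adjusted p-value plot of a model comparison
#'
#' Finner-adjusted p-values per comparison with the significance level.
#'
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_comparison <- function(object, ...) {
  cmp <- object$finner$comparisons
  cmp$treatment <- factor(cmp$treatment, levels = rev(cmp$treatment))
  ggplot2::ggplot(cmp, ggplot2::aes(x = .data$p_adjusted,
                                    y = .data$treatment)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = "dashed") +
    ggplot2::labs(x = "Finner-adjusted p-value", y = NULL,
                  title = paste("control:", object$finner$control)) +
    ggplot2::theme_minimal()
}

#' Render a gel image with its ROIs
#'
#' Raster view of a simulated gel with ROI bounding boxes coloured by
#' label; a quick visual sanity check of the simulator.
#'
#' @param dataset A `gel_dataset`.
#' @param image_id Which image to draw.
#' @return A ggplot.
#' @export
plot_gel_image <- function(dataset, image_id = 1) {
  img <- dataset$images[[image_id]]
  df <- tibble::tibble(row = rep(seq_len(nrow(img)), times = ncol(img)),
                       col = rep(seq_len(ncol(img)), each = nrow(img)),
                       grey = as.vector(img))
  rois <- dataset$rois[dataset$rois$image_id == image_id, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$grey)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::geom_rect(data = rois, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$col0 + 0.5,
                                    xmax = .data$col1 + 0.5,
                                    ymin = .data$row0 + 0.5,
                                    ymax = .data$row1 + 0.5,
                                    colour = .data$label),
                       fill = NA, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
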