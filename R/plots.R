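# ggplot2 views of the tabular results.

#' @importFrom rlang .data
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training curves
#'
#' Training loss, training Dice and validation Dice against the epoch, in
#' the style of the usual convergence plot; the best epoch is marked.
#'
#' @param object A `scau_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scau_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log,
                              cols = c("train_loss", "train_dice", "val_dice"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training progress",
                  subtitle = sprintf("best validation Dice %.3f at epoch %d",
                                     object$best_val_dice, object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Per-image metric distributions
#'
#' @param object A `scau_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scau_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("dice", "jaccard", "rvd"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-image segmentation metrics") +
    ggplot2::theme_minimal()
}

#' Ablation comparison
#'
#' Test-set mean Dice and Jaccard for the four attention arms.
#'
#' @param object A `scau_ablation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scau_ablation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("arm", "dice", "jaccard")],
    cols = c("dice", "jaccard"), names_to = "metric", values_to = "value")
  long$arm <- factor(long$arm, levels = c("none", "CA", "SA", "SA+CA"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$arm, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Attention ablation (test-set means)") +
    ggplot2::theme_minimal()
}
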