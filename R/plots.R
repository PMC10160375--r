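#' Plot group comparisons
#'
#' Dot plot of permutation p-values by metric and region, with the two
#' significance tiers marked.
#'
#' @param object A `sa_comparisons` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sa_comparisons <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
                     metric = factor(.data$metric, levels = .metric_order,
                                     labels = .metric_labels[.metric_order]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$metric)) +
    ggplot2::geom_point(ggplot2::aes(size = -log10(.data$p),
                                     colour = .data$p < 0.1)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey60"),
                                 name = "p < 0.1") +
    ggplot2::labs(x = "Region", y = NULL, size = "-log10 p",
                  title = "Permutation screening of band-ratio metrics") +
    ggplot2::theme_minimal()
}

#' Plot an elimination trace
#'
#' RMSE and relative error against the number of retained features; the
#' RMSE minimiser is highlighted.
#'
#' @param object An `elimination_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elimination_trace <- function(object, ...) {
  d <- tidyr::pivot_longer(tidy(object), c("rmse", "re"),
                           names_to = "criterion", values_to = "value")
  best <- object$n_features[which.min(object$rmse)]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_features, y = .data$value,
                                  colour = .data$criterion)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = best, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "Retained features", y = "Error",
                  title = "Backward elimination") +
    ggplot2::theme_minimal()
}

#' Scree plot of a principal-component basis
#'
#' @param object A `pca_basis`.
#' @param threshold Cumulative-contribution threshold drawn as a reference
#'   line (fraction).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_basis <- function(object, threshold = 0.877, ...) {
  d <- tidy(object)
  d$component <- factor(d$component, levels = d$component)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$contribution), fill = "#2166ac") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::geom_hline(yintercept = 100 * threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Contribution (%)",
                  title = "Variance contributions") +
    ggplot2::theme_minimal()
}

#' Plot training curves
#'
#' Per-iteration batch loss with per-epoch train/test accuracy overlay.
#'
#' @param object A `cnn_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cnn_model <- function(object, ...) {
  acc <- tidyr::pivot_longer(object$epoch_trajectory,
                             c("train_acc", "test_acc"),
                             names_to = "set", values_to = "accuracy")
  ggplot2::ggplot() +
    ggplot2::geom_line(data = object$loss_trajectory,
                       ggplot2::aes(x = .data$iteration, y = .data$loss),
                       colour = "grey70") +
    ggplot2::geom_line(data = acc,
                       ggplot2::aes(x = .data$iteration, y = .data$accuracy,
                                    colour = .data$set)) +
    ggplot2::labs(x = "Iteration", y = "Loss / accuracy",
                  title = "Training trajectory") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object An `eval_report` containing ROC points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc)) stop("report has no ROC points", call. = FALSE)
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Box plots of a method comparison
#'
#' Distribution of each evaluation metric per classifier over repeats.
#'
#' @param object A `method_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.method_comparison <- function(object, ...) {
  d <- tidyr::pivot_longer(object$runs,
                           c("acc", "tpr", "tnr", "mcc", "f1", "kappa", "auc"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$value,
                                  fill = .data$method)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Classifier comparison") +
    ggplot2::theme_minimal()
}
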