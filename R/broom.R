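#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a principal-component basis
#'
#' @param x A `pca_basis`.
#' @param ... Unused.
#' @return One row per component: `component`, `eigenvalue`,
#'   `contribution`, `cumulative`.
#' @export
tidy.pca_basis <- function(x, ...) {
  tibble::tibble(
    component = paste0("F", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    contribution = x$contribution,
    cumulative = x$cumulative)
}

#' @rdname tidy.pca_basis
#' @export
glance.pca_basis <- function(x, ...) {
  tibble::tibble(n_features = length(x$features),
                 n_components = length(x$eigenvalues))
}

#' Tidy an elimination trace
#'
#' @param x An `elimination_trace`.
#' @param ... Unused.
#' @return Tibble `n_features`, `dropped`, `rmse`, `re` (the list-column of
#'   retained sets is dropped).
#' @export
tidy.elimination_trace <- function(x, ...) {
  tibble::as_tibble(x)[c("n_features", "dropped", "rmse", "re")]
}

#' Tidy a trained network's training history
#'
#' @param x A `cnn_model`.
#' @param ... Unused.
#' @return The per-epoch trajectory (iteration, loss, learning rate,
#'   train/test accuracy).
#' @export
tidy.cnn_model <- function(x, ...) x$epoch_trajectory

#' @rdname tidy.cnn_model
#' @export
glance.cnn_model <- function(x, ...) {
  fin <- utils::tail(x$epoch_trajectory, 1)
  tibble::tibble(
    fused = x$fused,
    iterations = nrow(x$loss_trajectory),
    final_loss = fin$loss %||% NA_real_,
    train_acc = fin$train_acc %||% NA_real_,
    test_acc = fin$test_acc %||% NA_real_)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Long tibble `metric`, `value` (including `auc` when present).
#' @export
tidy.eval_report <- function(x, ...) {
  wide <- x$metrics
  if (!is.null(x$auc)) wide$auc <- x$auc
  tidyr::pivot_longer(wide, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  out <- x$metrics
  if (!is.null(x$auc)) out$auc <- x$auc
  dplyr::bind_cols(tibble::as_tibble(x$counts), out)
}

#' Tidy a method comparison
#'
#' @param x A `method_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the per-repeat runs; `glance()`: the mean summary
#'   table (one row per method).
#' @export
tidy.method_comparison <- function(x, ...) x$runs

#' @rdname tidy.method_comparison
#' @export
glance.method_comparison <- function(x, ...) x$summary
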