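#' Confusion counts for binary predictions
#'
#' Standard definitions with the positive class being the at-risk, low
#' situation-awareness state: TP = positive observed and predicted,
#' TN = negative observed and predicted, FP = negative observed but
#' predicted positive, FN = positive observed but predicted negative.
#'
#' @param labels Observed binary labels.
#' @param predictions Predicted binary labels.
#' @param positive The positive class (default `"low"`).
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions, positive = "low") {
  labels <- as.character(labels); predictions <- as.character(predictions)
  if (length(labels) != length(predictions)) stop("length mismatch", call. = FALSE)
  classes <- unique(c(labels, predictions))
  if (length(classes) > 2) stop("inputs must be binary", call. = FALSE)
  if (!positive %in% classes) stop("positive class absent from inputs", call. = FALSE)
  obs_pos <- labels == positive
  pred_pos <- predictions == positive
  list(tp = sum(obs_pos & pred_pos), fp = sum(!obs_pos & pred_pos),
       tn = sum(!obs_pos & !pred_pos), fn = sum(obs_pos & !pred_pos))
}

#' Classification metrics from confusion counts
#'
#' `ACC = (TP+TN)/n`, `TPR = TP/(TP+FN)` (sensitivity),
#' `TNR = TN/(TN+FP)` (specificity), plus the Matthews correlation
#' coefficient, F1 score and Cohen's kappa by their textbook formulas.
#' Any ratio with a zero denominator is reported as `NaN`, never silently
#' zero.
#'
#' @param counts List from [confusion()].
#' @return Tibble with one row: `acc`, `tpr`, `tnr`, `mcc`, `f1`, `kappa`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion table", call. = FALSE)
  safe_div <- function(a, b) if (b == 0) NaN else a / b
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  p_yes <- (tp + fp) / n * (tp + fn) / n
  p_no <- (tn + fn) / n * (tn + fp) / n
  pe <- p_yes + p_no
  acc <- (tp + tn) / n
  tibble::tibble(
    acc = acc,
    tpr = safe_div(tp, tp + fn),
    tnr = safe_div(tn, tn + fp),
    mcc = if (mcc_den == 0) NaN else (tp * tn - fp * fn) / mcc_den,
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    kappa = if (pe == 1) NaN else (acc - pe) / (1 - pe)
  )
}

#' ROC curve and AUC
#'
#' Sweeps every score threshold to build the ROC curve and computes the
#' AUC as the probability that a positive sample outranks a negative one
#' (rank statistic; ties count one half).
#'
#' @param labels Binary labels.
#' @param scores Numeric scores, higher = more positive.
#' @param positive The positive class (default `"low"`).
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(labels, scores, positive = "low") {
  labels <- as.character(labels)
  if (length(labels) != length(scores)) stop("length mismatch", call. = FALSE)
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- tibble::tibble(
    threshold = th,
    tpr = vapply(th, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  )
  list(roc = roc, auc = auc)
}

#' Full evaluation report for one classifier
#'
#' @param labels Observed labels.
#' @param predictions Predicted labels.
#' @param scores Positive-class scores (for ROC/AUC); optional.
#' @param positive Positive class.
#' @return An `eval_report`: confusion counts, metric tibble, ROC and AUC.
#' @export
eval_report <- function(labels, predictions, scores = NULL, positive = "low") {
  counts <- confusion(labels, predictions, positive)
  out <- list(counts = counts, metrics = classification_metrics(counts))
  if (!is.null(scores)) {
    ra <- roc_auc(labels, scores, positive)
    out$roc <- ra$roc
    out$auc <- ra$auc
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<eval_report> ACC %.3f TPR %.3f TNR %.3f MCC %.3f F1 %.3f Kappa %.3f%s\n",
    m$acc, m$tpr, m$tnr, m$mcc, m$f1, m$kappa,
    if (!is.null(x$auc)) sprintf(" AUC %.3f", x$auc) else ""))
  invisible(x)
}

#' Compare RF, plain CNN and hybrid RF-CNN classifiers
#'
#' Trains three classifiers on identical splits of one feature table and
#' repeats over derived seeds: a random forest on all features, a plain
#' (unfused) CNN on maps built from the raw standardised features, and the
#' full hybrid: RF importance elimination, PCA combination and the
#' PCA-fused CNN. Reports the per-repeat metric distributions and their
#' means.
#'
#' @param features Epoch-level feature tibble from [extract_features()]
#'   (rows from several subjects bound together).
#' @param n_trees,max_depth Forest hyperparameters.
#' @param pca_threshold Cumulative-contribution threshold for component
#'   selection.
#' @param cnn_cfg A [cnn_config()] (its `input_shape`/`stack` follow
#'   `build_cnn_inputs()` defaults).
#' @param stack,stride Epoch stacking for CNN inputs.
#' @param repeats Number of repeated runs (fresh split + training each).
#' @param seed Master seed.
#' @return A `method_comparison`: list with `runs` (tibble method x repeat
#'   x metrics) and `summary` (mean table, one row per method).
#' @export
compare_methods <- function(features, n_trees = 11, max_depth = 10,
                            pca_threshold = 0.877,
                            cnn_cfg = cnn_config(), stack = 20,
                            stride = stack, repeats = 3, seed = 1) {
  stopifnot(repeats >= 1)
  feat_cols <- setdiff(names(features),
                       c("subject_id", "group", "epoch_index",
                         "window_start_s"))
  y <- factor(features$group)
  runs <- purrr::map_dfr(seq_len(repeats), function(r) {
    rs <- derive_seed(seed, "rep", r)
    dplyr::bind_rows(
      rf_run(features[feat_cols], y, n_trees, max_depth, rs),
      cnn_run(features, feat_cols, y, cnn_cfg, stack, stride, rs,
              fused = FALSE),
      rfcnn_run(features, feat_cols, y, n_trees, max_depth, pca_threshold,
                cnn_cfg, stack, stride, rs)
    ) |> dplyr::mutate(repeat_id = r)
  })
  summary <- runs |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(dplyr::across(c("acc", "tpr", "tnr", "mcc", "f1",
                                     "kappa", "auc"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  structure(list(runs = runs, summary = summary), class = "method_comparison")
}

rf_run <- function(X, y, n_trees, max_depth, seed) {
  n <- length(y)
  tr <- with_seed(derive_seed(seed, "rf-split"), {
    unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv); sample(idx, max(1, round(0.75 * length(idx))))
    }))
  })
  te <- setdiff(seq_len(n), tr)
  dat <- data.frame(X, .y = y, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = dat[tr, ],
                        num.trees = n_trees, max.depth = max_depth,
                        probability = TRUE, seed = derive_seed(seed, "rf"),
                        num.threads = 1, verbose = FALSE)
  positive <- positive_level(y)
  sc <- stats::predict(fit, dat[te, ])$predictions[, positive]
  pred <- ifelse(sc >= 0.5, positive, setdiff(levels(y), positive)[1])
  rep <- eval_report(y[te], pred, sc, positive)
  dplyr::bind_cols(tibble::tibble(method = "RF"), rep$metrics,
                   tibble::tibble(auc = rep$auc))
}

cnn_run <- function(features, feat_cols, y, cnn_cfg, stack, stride, seed,
                    fused = FALSE) {
  Z <- scale(as.matrix(features[feat_cols]))
  scores <- dplyr::bind_cols(
    features[c("subject_id", "group", "epoch_index")],
    tibble::as_tibble(as.data.frame(Z)))
  inputs <- build_cnn_inputs(scores, shape = cnn_cfg$input_shape,
                             stack = stack, stride = stride)
  model <- train_cnn(inputs, config = cnn_cfg,
                     seed = derive_seed(seed, "cnn"), fusion = fused)
  score_model(model, inputs, if (fused) "RF-CNN" else "CNN")
}

rfcnn_run <- function(features, feat_cols, y, n_trees, max_depth,
                      pca_threshold, cnn_cfg, stack, stride, seed) {
  trace <- backward_eliminate(features[feat_cols], y, n_trees, max_depth,
                              seed = derive_seed(seed, "elim"))
  kept <- retained_features(trace)
  basis <- fit_pca(features[kept])
  k <- select_k(basis, threshold = pca_threshold)
  sc <- pca_scores(basis, features[kept], k)
  colnames(sc) <- paste0("PC", seq_len(k))
  scores <- dplyr::bind_cols(
    features[c("subject_id", "group", "epoch_index")],
    tibble::as_tibble(as.data.frame(sc)))
  inputs <- build_cnn_inputs(scores, shape = cnn_cfg$input_shape,
                             stack = stack, stride = stride)
  model <- train_cnn(inputs, config = cnn_cfg,
                     seed = derive_seed(seed, "fcnn"), fusion = TRUE)
  score_model(model, inputs, "RF-CNN")
}

score_model <- function(model, inputs, method) {
  te <- model$test_idx
  labs <- model$labels[te]
  pred <- predict_cnn(model, inputs$maps[te])
  positive <- if ("low" %in% model$levels) "low" else model$levels[2]
  rep <- eval_report(labs, pred$label, pred$score, positive)
  dplyr::bind_cols(tibble::tibble(method = method), rep$metrics,
                   tibble::tibble(auc = rep$auc))
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> over", max(x$runs$repeat_id), "repeats\n")
  print(x$summary)
  invisible(x)
}
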