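#' Grid search for random-forest hyperparameters
#'
#' Cross-validated accuracy over a grid of ensemble sizes and tree depths;
#' the returned spec maximises mean CV accuracy (ties broken toward the
#' smaller ensemble, then the shallower tree).
#'
#' @param X Feature tibble/data frame (numeric columns only).
#' @param y Binary labels (factor or coercible).
#' @param n_trees_grid,max_depth_grid Integer grids (defaults 1-50 and
#'   1-20).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed controlling fold assignment and forest fits.
#' @param groups Optional grouping vector (e.g. subject ids); when given,
#'   folds are assigned at the group level to avoid within-subject leakage.
#' @return List with `n_trees`, `max_depth`, `score` (best mean CV
#'   accuracy) and `surface` (tibble `n_trees`, `max_depth`, `score`).
#' @export
rf_grid_search <- function(X, y, n_trees_grid = 1:50, max_depth_grid = 1:20,
                           folds = 5, seed = 1, groups = NULL) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("y must contain both classes", call. = FALSE)
  fold_id <- make_folds(y, folds, derive_seed(seed, "folds"), groups)
  grid <- tidyr::expand_grid(n_trees = n_trees_grid, max_depth = max_depth_grid)
  dat <- data.frame(X, .y = y, check.names = FALSE)
  score <- purrr::pmap_dbl(grid, function(n_trees, max_depth) {
    accs <- vapply(seq_len(folds), function(k) {
      tr <- fold_id != k
      if (nlevels(droplevels(y[tr])) < 2) return(NA_real_)
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dat[tr, ],
        num.trees = n_trees, max.depth = max_depth,
        seed = derive_seed(seed, "fit", n_trees, max_depth, k),
        num.threads = 1, verbose = FALSE)
      mean(stats::predict(fit, dat[!tr, ])$predictions == y[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  })
  surface <- dplyr::mutate(grid, score = score)
  best <- surface[order(-surface$score, surface$n_trees, surface$max_depth), ][1, ]
  list(n_trees = best$n_trees, max_depth = best$max_depth,
       score = best$score, surface = surface)
}

make_folds <- function(y, folds, seed, groups = NULL) {
  with_seed(seed, {
    if (!is.null(groups)) {
      g <- unique(groups)
      gf <- stats::setNames(sample(rep_len(seq_len(folds), length(g))), g)
      unname(gf[as.character(groups)])
    } else {
      # stratified: shuffle within class, deal round-robin
      id <- integer(length(y))
      for (lev in levels(y)) {
        idx <- sample(which(y == lev))
        id[idx] <- rep_len(seq_len(folds), length(idx))
      }
      id
    }
  })
}

#' Out-of-bag noise-injection feature importance
#'
#' Fits a random forest with bootstrap sampling, then scores each feature
#' by how much the out-of-bag (OOB) error grows after noise is injected
#' into it: the feature's values are permuted across samples, every tree is
#' re-scored on its own OOB rows, and the importance is
#' `sum_trees(errOOB2 - errOOB1) / Ntree`. Trees with an empty OOB set are
#' skipped and `Ntree` adjusted.
#'
#' @param X Feature tibble (numeric columns).
#' @param y Binary labels.
#' @param n_trees,max_depth Forest hyperparameters (e.g. from
#'   [rf_grid_search()]).
#' @param seed Integer seed (forest fit and permutations).
#' @return Tibble `feature`, `importance`, sorted decreasing.
#' @export
oob_importance <- function(X, y, n_trees = 11, max_depth = 10, seed = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("y must contain both classes", call. = FALSE)
  dat <- data.frame(X, .y = y, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = n_trees, max.depth = max_depth, keep.inbag = TRUE,
    seed = derive_seed(seed, "forest"), num.threads = 1, verbose = FALSE)
  inbag <- do.call(cbind, fit$inbag.counts)   # n x ntrees
  oob <- inbag == 0
  base_pred <- stats::predict(fit, dat, predict.all = TRUE,
                              num.threads = 1)$predictions
  y_int <- as.integer(y)
  live <- colSums(oob) > 0
  if (!any(live)) stop("no tree has out-of-bag samples", call. = FALSE)
  err1 <- vapply(which(live), function(t) {
    mean(base_pred[oob[, t], t] != y_int[oob[, t]])
  }, numeric(1))

  feats <- colnames(X)
  imp <- vapply(seq_along(feats), function(j) {
    dat_perm <- dat
    dat_perm[[feats[j]]] <- with_seed(derive_seed(seed, "perm", j), {
      sample(dat_perm[[feats[j]]])
    })
    pred2 <- stats::predict(fit, dat_perm, predict.all = TRUE,
                            num.threads = 1)$predictions
    err2 <- vapply(which(live), function(t) {
      mean(pred2[oob[, t], t] != y_int[oob[, t]])
    }, numeric(1))
    sum(err2 - err1) / sum(live)
  }, numeric(1))

  tibble::tibble(feature = feats, importance = imp) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Normalised root-mean-square error and relative error
#'
#' `paper_rmse()` computes the normalised criterion used to score feature
#' subsets during elimination:
#' `RMSE = sqrt( sum((y_obs - y_pred)^2) / sum((y_obs - mean(y_pred))^2) )`
#' (note the prediction-mean in the denominator, which makes the score
#' invariant to a common shift of both vectors), together with the relative
#' error `RE = mean(|y_obs - y_pred|) / range(y_obs)`.
#' `conventional_rmse()` is the textbook root-mean-square error, provided
#' for reference; only `paper_rmse()` drives elimination.
#'
#' @param y_obs,y_pred Numeric vectors of equal length (n >= 2).
#' @return `paper_rmse()`: list with `rmse` and `re`.
#' @export
paper_rmse <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (length(y_obs) < 2) stop("need n >= 2", call. = FALSE)
  denom <- sum((y_obs - mean(y_pred))^2)
  if (denom == 0) stop("degenerate denominator: observations equal the mean prediction",
                       call. = FALSE)
  rng <- diff(range(y_obs))
  if (rng == 0) stop("zero label range", call. = FALSE)
  list(rmse = sqrt(sum((y_obs - y_pred)^2) / denom),
       re = mean(abs(y_obs - y_pred)) / rng)
}

#' @rdname paper_rmse
#' @export
conventional_rmse <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) stop("length mismatch", call. = FALSE)
  sqrt(mean((y_obs - y_pred)^2))
}

# Cross-validated probability predictions (positive class) for a feature
# subset.
cv_rf_scores <- function(X, y, n_trees, max_depth, fold_id, seed,
                         positive = positive_level(y)) {
  dat <- data.frame(X, .y = y, check.names = FALSE)
  pred <- numeric(length(y))
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat[tr, ],
      num.trees = n_trees, max.depth = max_depth, probability = TRUE,
      seed = derive_seed(seed, "cv", k), num.threads = 1, verbose = FALSE)
    p <- stats::predict(fit, dat[!tr, ])$predictions
    pred[!tr] <- p[, positive]
  }
  pred
}

# Positive class is "low" situation awareness (the at-risk state) when
# present, otherwise the factor's last level.
positive_level <- function(y) {
  y <- droplevels(as.factor(y))
  if ("low" %in% levels(y)) "low" else levels(y)[nlevels(y)]
}

#' Backward feature elimination by out-of-bag importance
#'
#' Starting from all features, repeatedly removes the feature with the
#' lowest current OOB noise-injection importance, refits, and records the
#' normalised RMSE and RE of cross-validated predictions for the remaining
#' set; for p initial features the trace has p-1 entries (counts p-1 down
#' to 1). The retained set is the one minimising RMSE. Importance ties are
#' broken by dropping the lexicographically last feature name (logged).
#'
#' @param X Feature tibble (>= 2 columns).
#' @param y Binary labels (`"high"`/`"low"` or factor).
#' @param n_trees,max_depth Forest hyperparameters.
#' @param folds CV folds used for scoring.
#' @param seed Integer seed.
#' @param groups Optional grouping vector for subject-level folds.
#' @return An `elimination_trace` tibble with columns `n_features`,
#'   `dropped`, `rmse`, `re` and list-column `retained`; the RMSE-minimising
#'   feature set is in attribute `retained_set` (see
#'   [retained_features()]).
#' @export
backward_eliminate <- function(X, y, n_trees = 11, max_depth = 10,
                               folds = 5, seed = 1, groups = NULL) {
  feats <- colnames(X)
  if (length(feats) < 2) stop("need >= 2 features", call. = FALSE)
  y <- droplevels(as.factor(y))
  positive <- positive_level(y)
  y_num <- as.numeric(y == positive)
  fold_id <- make_folds(y, folds, derive_seed(seed, "elim-folds"), groups)
  current <- feats
  rows <- list()
  round <- 0
  while (length(current) > 1) {
    round <- round + 1
    imp <- oob_importance(X[current], y, n_trees, max_depth,
                          seed = derive_seed(seed, "imp", round))
    lowest <- imp$feature[imp$importance == min(imp$importance)]
    if (length(lowest) > 1) {
      lowest <- sort(lowest)[length(lowest)]
      message("importance tie broken by name: dropping ", lowest)
    }
    current <- setdiff(current, lowest)
    scores <- cv_rf_scores(X[current], y, n_trees, max_depth, fold_id,
                           seed = derive_seed(seed, "score", round),
                           positive = positive)
    err <- paper_rmse(y_num, scores)
    rows[[round]] <- tibble::tibble(
      n_features = length(current), dropped = lowest,
      rmse = err$rmse, re = err$re, retained = list(current))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "retained_set") <- out$retained[[which.min(out$rmse)]]
  class(out) <- c("elimination_trace", class(out))
  out
}

#' Feature set retained by an elimination trace
#'
#' @param trace An `elimination_trace` from [backward_eliminate()].
#' @return Character vector: the retained feature names (RMSE minimiser).
#' @export
retained_features <- function(trace) {
  attr(trace, "retained_set")
}
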