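#' Principal-component basis of a feature table
#'
#' Correlation-matrix PCA: features are z-scored (ratio metrics live on
#' heterogeneous scales and the unit-norm loading constraint presumes
#' standardised inputs), components are ordered by decreasing eigenvalue,
#' and each loading row's largest-magnitude entry is made positive for a
#' reproducible orientation. Component scores are mutually uncorrelated.
#'
#' @param X Feature tibble/matrix (numeric, >= 2 rows).
#' @return A `pca_basis`: list with `loadings` (component x feature,
#'   orthonormal rows), `eigenvalues`, `contribution` (% of total
#'   variance), `cumulative` (%), `center`, `scale`, `features` and
#'   `scores` (row x component).
#' @examples
#' b <- fit_pca(data.frame(x = rnorm(50), y = rnorm(50)))
#' b$contribution
#' @export
fit_pca <- function(X) {
  X <- as.data.frame(X)
  if (nrow(X) < 2) stop("need >= 2 rows", call. = FALSE)
  if (!ncol(X)) stop("need >= 1 column", call. = FALSE)
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(names(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  loadings <- t(pc$rotation)            # component x feature
  # sign convention: largest-|entry| of each row positive
  flips <- apply(loadings, 1, function(r) sign(r[which.max(abs(r))]))
  loadings <- loadings * flips
  scores <- sweep(pc$x, 2, flips, `*`)
  ev <- pc$sdev^2
  contribution <- 100 * ev / sum(ev)
  structure(
    list(loadings = loadings, eigenvalues = ev,
         contribution = contribution,
         cumulative = cumulative_contribution(contribution),
         center = pc$center, scale = pc$scale,
         features = colnames(X), scores = scores),
    class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat("<pca_basis> ", length(x$features), " features, ",
      length(x$eigenvalues), " components; cumulative contribution: ",
      paste(sprintf("%.1f", x$cumulative), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Running sum of variance contributions
#'
#' @param contributions Per-component variance contributions in percent.
#' @return Cumulative contributions (same length).
#' @examples
#' cumulative_contribution(c(25.108, 17.233, 14.176, 11.548, 10.016, 9.624))
#' @export
cumulative_contribution <- function(contributions) {
  if (any(contributions < 0)) stop("contributions must be >= 0", call. = FALSE)
  cumsum(contributions)
}

#' Number of components reaching a cumulative-contribution threshold
#'
#' @param basis A `pca_basis` (or anything with a `cumulative` element in
#'   percent).
#' @param threshold Cumulative-contribution threshold as a fraction in
#'   `(0, 1]` (default 0.877).
#' @param k Optional fixed component count; when supplied it wins over the
#'   threshold.
#' @return Integer k: the smallest component count whose cumulative
#'   contribution reaches the threshold.
#' @export
select_k <- function(basis, threshold = 0.877, k = NULL) {
  if (!is.null(k)) {
    if (k < 1 || k > length(basis$cumulative)) {
      stop("k out of range", call. = FALSE)
    }
    return(as.integer(k))
  }
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]",
                                            call. = FALSE)
  hit <- which(basis$cumulative >= 100 * threshold - 1e-9)
  if (!length(hit)) stop("threshold unattainable: cumulative contribution tops out at ",
                         sprintf("%.3f%%", max(basis$cumulative)), call. = FALSE)
  hit[1]
}

#' Composite component weights
#'
#' Weights the k retained components by their share of the retained
#' variance: `w_j = contribution_j / sum_{i<=k} contribution_i`. The
#' weights are positive, non-increasing and sum to one, and define the
#' composite score `F = sum_j w_j F_j`.
#'
#' @param basis A `pca_basis`, or a bare numeric vector of per-component
#'   contributions in percent.
#' @param k Number of retained components.
#' @return Numeric weight vector of length k.
#' @examples
#' composite_weights(c(25.108, 17.233, 14.176, 11.548, 10.016, 9.624), k = 6)
#' @export
composite_weights <- function(basis, k) {
  contrib <- if (is.numeric(basis)) basis else basis$contribution
  if (k < 1 || k > length(contrib)) stop("k out of range", call. = FALSE)
  w <- contrib[seq_len(k)] / sum(contrib[seq_len(k)])
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  w
}

#' Project a feature table onto a fitted basis
#'
#' @param basis A `pca_basis`.
#' @param X New feature data with the basis's feature columns.
#' @param k Number of components to keep (default all).
#' @return Matrix of component scores (rows x k).
#' @export
pca_scores <- function(basis, X, k = length(basis$eigenvalues)) {
  X <- as.matrix(as.data.frame(X)[basis$features])
  Z <- sweep(sweep(X, 2, basis$center), 2, basis$scale, `/`)
  (Z %*% t(basis$loadings))[, seq_len(k), drop = FALSE]
}

#' Assemble classifier input maps from component scores
#'
#' Stacks `stack` consecutive same-subject epochs' k-dimensional score
#' vectors as the columns of a 2-D map, zero-pads to `shape`, and min-max
#' scales each component row to `[0, 1]` across the data set. Each map is
#' one classifier sample, labelled with the subject's group.
#'
#' @param scores Tibble with `subject_id`, `group`, `epoch_index` and one
#'   numeric column per component (e.g. from [pca_scores()] bound to the
#'   epoch metadata), or a matrix plus `subject_id`/`group` vectors.
#' @param shape Output map shape `c(rows, cols)` (default `c(13, 20)`).
#' @param stack Epochs per sample (columns filled; default 20).
#' @param stride Epoch step between consecutive samples of one subject
#'   (default `stack`, i.e. non-overlapping samples).
#' @return A `cnn_input_set`: list with `maps` (list of `shape` matrices),
#'   `labels` (factor high/low), `subject_id` character vector, and the
#'   scaling used.
#' @export
build_cnn_inputs <- function(scores, shape = c(13, 20), stack = 20,
                             stride = stack) {
  stopifnot(is.data.frame(scores),
            all(c("subject_id", "group") %in% names(scores)))
  comp_cols <- setdiff(names(scores), c("subject_id", "group", "epoch_index",
                                        "window_start_s"))
  k <- length(comp_cols)
  if (shape[1] < k || shape[2] < stack) {
    stop("shape smaller than (components, stack)", call. = FALSE)
  }
  M <- as.matrix(scores[comp_cols])
  lo <- apply(M, 2, min); hi <- apply(M, 2, max)
  rngs <- ifelse(hi - lo == 0, 1, hi - lo)
  M <- sweep(sweep(M, 2, lo), 2, rngs, `/`)

  maps <- list(); labels <- character(0); subjects <- character(0)
  for (sid in unique(scores$subject_id)) {
    rows <- which(scores$subject_id == sid)
    grp <- scores$group[rows[1]]
    n_ep <- length(rows)
    if (n_ep < stack) next
    starts <- seq(1, n_ep - stack + 1, by = stride)
    for (s in starts) {
      m <- matrix(0, shape[1], shape[2])
      m[seq_len(k), seq_len(stack)] <- t(M[rows[s:(s + stack - 1)], , drop = FALSE])
      maps[[length(maps) + 1]] <- m
      labels <- c(labels, grp)
      subjects <- c(subjects, sid)
    }
  }
  if (!length(maps)) {
    stop("not enough epochs per subject to form one stacked sample",
         call. = FALSE)
  }
  structure(list(maps = maps, labels = factor(labels),
                 subject_id = subjects, shape = shape, stack = stack,
                 scaling = list(lo = lo, range = rngs)),
            class = "cnn_input_set")
}

#' @export
print.cnn_input_set <- function(x, ...) {
  cat("<cnn_input_set> ", length(x$maps), " maps of ", x$shape[1], "x",
      x$shape[2], " (", paste(levels(x$labels), table(x$labels),
                              sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}
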