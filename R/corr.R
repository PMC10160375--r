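#' Welch's t statistic
#'
#' `t = (mean(a) - mean(b)) / sqrt(s_a^2/n_a + s_b^2/n_b)` with n-1
#' variance denominators. When both samples are constant the statistic is 0
#' for equal means and signed infinity otherwise (flagged with a warning).
#'
#' @param a,b Numeric samples of length >= 2.
#' @return The t statistic (length-1 numeric).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need >= 2 observations", call. = FALSE)
  }
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  d <- mean(a) - mean(b)
  if (se2 == 0) {
    if (d == 0) return(0)
    warning("zero variance with unequal means: statistic is infinite")
    return(sign(d) * Inf)
  }
  d / sqrt(se2)
}

# Vectorised |Welch t| over permutations: columns of `perm` are index
# permutations of the pooled sample; the first na entries form group a.
welch_t_perms <- function(pooled, perm, na) {
  nb <- length(pooled) - na
  x <- matrix(pooled[perm], nrow = nrow(perm))
  a <- x[seq_len(na), , drop = FALSE]
  b <- x[(na + 1):nrow(x), , drop = FALSE]
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a^2) - na * ma^2) / (na - 1)
  vb <- (colSums(b^2) - nb * mb^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  t[se2 == 0] <- 0
  t
}

#' Two-sided permutation p-value for a group difference
#'
#' Shuffles group labels across the pooled sample `n_perm` times and
#' compares each permuted Welch statistic with the observed one:
#' `p = (1 + #{|t*| >= |t_obs|}) / (n_perm + 1)`. The additive-one
#' correction keeps p strictly positive.
#'
#' @param a,b Numeric samples.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return p-value in `(0, 1]`.
#' @export
permutation_p <- function(a, b, n_perm = 10000, seed = 1) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  t_obs <- abs(welch_t(a, b))
  pooled <- c(a, b)
  n <- length(pooled)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  t_star <- abs(welch_t_perms(pooled, perm, length(a)))
  (1 + sum(t_star >= t_obs - 1e-12)) / (n_perm + 1)
}

#' Group comparison of ratio metrics per region
#'
#' For every (metric, region) combination, compares the subject-level metric
#' means of the high- and low-SA groups: group means and SDs, Welch's t and
#' a two-sided permutation p-value, with dual significance tiers
#' (`"a"` p < 0.05, `"b"` p < 0.1).
#'
#' @param subject_values Tibble from [subject_metric_means()]: columns
#'   `subject_id`, `group` (`"high"`/`"low"`), `region`, `metric`, `value`.
#' @param metrics,regions Combinations to test (defaults: the five metrics
#'   over F, C, P, O -- 20 comparisons).
#' @param n_perm Permutations per comparison.
#' @param seed Master seed; each comparison gets a derived substream.
#' @return A `sa_comparisons` tibble: `metric`, `region`, `mean_high`,
#'   `sd_high`, `mean_low`, `sd_low`, `t`, `p`, `tier`.
#' @export
evaluate_correlations <- function(subject_values,
                                  metrics = ratio_metric_names(),
                                  regions = c("F", "C", "P", "O"),
                                  n_perm = 10000, seed = 1) {
  stopifnot(all(c("subject_id", "group", "region", "metric", "value")
                %in% names(subject_values)))
  missing_regions <- setdiff(regions, unique(subject_values$region))
  if (length(missing_regions)) {
    stop("no data for region(s): ", paste(missing_regions, collapse = ", "),
         call. = FALSE)
  }
  out <- tidyr::expand_grid(metric = metrics, region = regions) |>
    purrr::pmap_dfr(function(metric, region) {
      d <- dplyr::filter(subject_values,
                         .data$metric == !!metric, .data$region == !!region)
      a <- d$value[d$group == "high"]
      b <- d$value[d$group == "low"]
      if (length(a) < 2 || length(b) < 2) {
        stop("need >= 2 subjects per group for ", metric, " in region ",
             region, call. = FALSE)
      }
      tibble::tibble(
        metric = metric, region = region,
        mean_high = mean(a), sd_high = stats::sd(a),
        mean_low = mean(b), sd_low = stats::sd(b),
        t = welch_t(a, b),
        p = permutation_p(a, b, n_perm = n_perm,
                          seed = derive_seed(seed, metric, region))
      )
    }) |>
    dplyr::mutate(tier = dplyr::case_when(.data$p < 0.05 ~ "a",
                                          .data$p < 0.1 ~ "b",
                                          TRUE ~ ""))
  class(out) <- c("sa_comparisons", class(out))
  out
}

#' Select correlated features from group comparisons
#'
#' Keeps the (metric, region) pairs with permutation p below the lenient
#' threshold in the selectable regions (frontal and central by default,
#' where group differences are most discriminative), and emits the mean and
#' median feature name for each per [feature_names()].
#'
#' @param comparisons Output of [evaluate_correlations()].
#' @param alpha_lenient Selection threshold on p (default 0.1, the lenient
#'   tier, so borderline frontal alpha/beta-type effects are retained).
#' @param regions_for_selection Regions eligible for selection.
#' @return Character vector of feature names (possibly empty), ordered
#'   metric-major as in [feature_names()]; the selected (metric, region)
#'   pairs are attached as attribute `pairs`.
#' @export
select_features <- function(comparisons, alpha_lenient = 0.1,
                            regions_for_selection = c("F", "C")) {
  sel <- dplyr::filter(comparisons,
                       .data$p < alpha_lenient,
                       .data$region %in% regions_for_selection)
  if (!nrow(sel)) {
    out <- character(0)
    attr(out, "pairs") <- sel[, c("metric", "region")]
    return(out)
  }
  fn <- feature_names(unique(sel$metric), unique(sel$region))
  fn <- dplyr::semi_join(fn, sel, by = c("metric", "region"))
  out <- fn$feature
  attr(out, "pairs") <- sel[, c("metric", "region")]
  out
}
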