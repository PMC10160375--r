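#' Feature names for selected metric-region pairs
#'
#' Builds the conventional feature-naming table: each selected
#' (metric, region) pair contributes a mean feature (`M`) and a median
#' feature (`P`), named `<region><stat><index>` where the index is the
#' metric's rank within the selected set in canonical metric order. With
#' the three classically selected metrics (alpha/beta, theta/(alpha+theta),
#' (alpha+theta)/beta) over regions F and C this yields the 12 names
#' FM1, FP1, CM1, CP1, ..., CP3.
#'
#' @param metrics Character vector of metric names (see
#'   [ratio_metric_names()]).
#' @param regions Character vector of region codes.
#' @return Tibble with columns `feature`, `metric`, `region`, `stat`
#'   (`"M"` mean, `"P"` median) and `index`.
#' @examples
#' feature_names()$feature
#' @export
feature_names <- function(metrics = c("alpha_beta", "theta_alphatheta",
                                      "alphatheta_beta"),
                          regions = c("F", "C")) {
  metrics <- unique(metrics)
  if (!all(metrics %in% .metric_order)) {
    stop("unknown metric(s): ",
         paste(setdiff(metrics, .metric_order), collapse = ", "),
         call. = FALSE)
  }
  if (!all(regions %in% .regions)) {
    stop("unknown region(s): ",
         paste(setdiff(regions, .regions), collapse = ", "), call. = FALSE)
  }
  metrics <- .metric_order[.metric_order %in% metrics]
  regions <- unique(regions)
  tidyr::expand_grid(
    metric = metrics, region = regions, stat = c("M", "P")
  ) |>
    dplyr::mutate(index = match(.data$metric, metrics),
                  feature = paste0(.data$region, .data$stat, .data$index)) |>
    dplyr::select("feature", "metric", "region", "stat", "index")
}

# Ratio-metric values for a set of equal-length segments.
# starts_samp is 0-based; returns array [segment, region, metric].
segment_ratio_values <- function(rec, starts_samp, sub_samples,
                                 regions, metrics, bands = eeg_bands()) {
  fs <- rec$sampling_rate
  dt <- 1 / fs
  nseg <- length(starts_samp)
  f <- (0:(sub_samples - 1)) * fs / sub_samples
  keep <- f > 0 & f <= fs / 2
  band_rows <- lapply(seq_len(nrow(bands)), function(i) {
    which(keep & f >= bands$lo[i] & f < bands$hi[i])
  })
  names(band_rows) <- bands$band

  idx <- outer(seq_len(sub_samples), starts_samp, `+`)
  bp <- array(0, dim = c(nrow(bands), nseg, length(regions)),
              dimnames = list(bands$band, NULL, regions))
  for (r in seq_along(regions)) {
    chans <- which(rec$channels$region == regions[r])
    if (!length(chans)) {
      stop("recording has no channels in region ", regions[r], call. = FALSE)
    }
    for (ch in chans) {
      seg <- matrix(rec$data[, ch][idx], nrow = sub_samples)
      S <- (dt / sub_samples) * Mod(stats::mvfft(seg))^2
      for (b in seq_along(band_rows)) {
        bp[b, , r] <- bp[b, , r] + colSums(S[band_rows[[b]], , drop = FALSE])
      }
    }
    bp[, , r] <- bp[, , r] / length(chans)
  }

  out <- array(NA_real_, dim = c(nseg, length(regions), length(metrics)),
               dimnames = list(NULL, regions, metrics))
  for (r in seq_along(regions)) {
    th <- bp["theta", , r]; al <- bp["alpha", , r]; be <- bp["beta", , r]
    vals <- rbind(
      theta_beta           = th / be,
      alpha_beta           = al / be,
      theta_alphatheta     = th / (al + th),
      alphatheta_beta      = (al + th) / be,
      alphatheta_alphabeta = (al + th) / (al + be)
    )
    out[, r, ] <- t(vals[metrics, , drop = FALSE])
  }
  out
}

#' Sliding-window feature table
#'
#' Slides a window (default 5 s, 50% overlap) over the recording, splits
#' each window into 1 s sub-epochs, computes the region-averaged band-ratio
#' metrics per sub-epoch, and summarises each (metric, region) pair by its
#' mean and median across the window's sub-epochs. Windows containing any
#' artifact-flagged sample are dropped.
#'
#' @param rec An `eeg_recording` (line-filtered; see [remove_line_noise()]).
#' @param window Window length in seconds.
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @param metrics,regions Metric and region sets defining the feature
#'   columns; defaults give the classical 12 features over F and C.
#' @param sub_epoch Sub-epoch length in seconds over which the within-window
#'   mean/median are taken.
#' @param mask Optional per-sample artifact mask; computed via
#'   [flag_artifacts()] when `NULL`.
#' @param bands Band definitions.
#' @return Tibble with `subject_id`, `group`, `epoch_index`,
#'   `window_start_s` and one column per feature (see [feature_names()]).
#' @export
extract_features <- function(rec, window = 5, overlap = 0.5,
                             metrics = c("alpha_beta", "theta_alphatheta",
                                         "alphatheta_beta"),
                             regions = c("F", "C"),
                             sub_epoch = 1, mask = NULL,
                             bands = eeg_bands()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  fs <- rec$sampling_rate
  n <- nrow(rec$data)
  wsamp <- round(window * fs)
  if (n < wsamp) stop("recording shorter than one window", call. = FALSE)
  if (is.null(mask)) mask <- flag_artifacts(rec)
  fn <- feature_names(metrics, regions)
  metrics <- unique(fn$metric)
  regions <- unique(fn$region)
  sub_samples <- round(sub_epoch * fs)
  nsub <- floor(window / sub_epoch)

  step <- max(round(window * (1 - overlap) * fs), 1)
  win_starts <- seq(0, n - wsamp, by = step)
  clean <- vapply(win_starts, function(s) !any(mask[(s + 1):(s + wsamp)]),
                  logical(1))
  if (!any(clean)) stop("all epochs are artifact-flagged", call. = FALSE)
  win_starts <- win_starts[clean]

  sub_starts <- lapply(win_starts, function(s) s + (0:(nsub - 1)) * sub_samples)
  all_starts <- unique(unlist(sub_starts))
  vals <- segment_ratio_values(rec, all_starts, sub_samples,
                               regions, metrics, bands)

  rows <- lapply(seq_along(win_starts), function(w) {
    seg_idx <- match(sub_starts[[w]], all_starts)
    out <- numeric(nrow(fn))
    for (i in seq_len(nrow(fn))) {
      v <- vals[seg_idx, fn$region[i], fn$metric[i]]
      out[i] <- if (fn$stat[i] == "M") mean(v) else stats::median(v)
    }
    out
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- fn$feature
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = rec$subject_id,
      group = rec$group %||% NA_character_,
      epoch_index = seq_along(win_starts),
      window_start_s = win_starts / fs
    ),
    tibble::as_tibble(mat)
  )
}

#' Subject-level metric means by region
#'
#' Computes each subject's mean band-ratio metric per region over all clean
#' 1 s sub-epochs of the recording. These subject-level values are the
#' permutation units for the group comparison: epochs within a subject are
#' dependent, so group statistics are taken over subjects.
#'
#' @param recordings List of `eeg_recording` objects (a cohort).
#' @param metrics,regions Metrics and regions to summarise (defaults: all
#'   five metrics over F, C, P, O).
#' @param line_filter Apply the 50 Hz notch before analysis (default TRUE).
#' @param sub_epoch Sub-epoch length in seconds.
#' @param bands Band definitions.
#' @return Tibble with columns `subject_id`, `group`, `region`, `metric`,
#'   `value`.
#' @export
subject_metric_means <- function(recordings,
                                 metrics = ratio_metric_names(),
                                 regions = c("F", "C", "P", "O"),
                                 line_filter = TRUE, sub_epoch = 1,
                                 bands = eeg_bands()) {
  purrr::map_dfr(recordings, function(rec) {
    if (line_filter) rec <- remove_line_noise(rec)
    mask <- flag_artifacts(rec)
    fs <- rec$sampling_rate
    sub_samples <- round(sub_epoch * fs)
    starts <- seq(0, nrow(rec$data) - sub_samples, by = sub_samples)
    clean <- vapply(starts, function(s) !any(mask[(s + 1):(s + sub_samples)]),
                    logical(1))
    if (!any(clean)) stop("all epochs are artifact-flagged for subject ",
                          rec$subject_id, call. = FALSE)
    vals <- segment_ratio_values(rec, starts[clean], sub_samples,
                                 regions, metrics, bands)
    tidyr::expand_grid(region = regions, metric = metrics) |>
      dplyr::mutate(
        subject_id = rec$subject_id,
        group = rec$group %||% NA_character_,
        value = purrr::map2_dbl(.data$region, .data$metric,
                                function(r, m) mean(vals[, r, m]))
      ) |>
      dplyr::select("subject_id", "group", "region", "metric", "value")
  })
}
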