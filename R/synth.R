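#' Group-level band-ratio calibration targets
#'
#' Per-region, per-group targets for the theta/beta and alpha/beta power
#' ratios used to calibrate the synthetic generator. `"observed"` uses the
#' reported group means of both ratios in all four analysed regions, so all
#' five derived ratio metrics differ between groups everywhere.
#' `"fc_only"` plants group differences only in the frontal and central
#' alpha/beta ratio (keeping theta/beta equal across groups and leaving the
#' parietal/occipital regions identical), which is the cleanest cohort a
#' power-ratio generator can produce for feature-recovery studies: because
#' every ratio metric is a function of one (theta, alpha, beta) power triple,
#' a group difference in alpha/beta necessarily moves theta/(alpha+theta),
#' (alpha+theta)/beta and, residually, (alpha+theta)/(alpha+beta) as well.
#'
#' @param plant `"observed"` or `"fc_only"`.
#' @return Tibble with columns `group`, `region`, `theta_beta`, `alpha_beta`.
#' @export
sa_ratio_targets <- function(plant = c("observed", "fc_only")) {
  plant <- match.arg(plant)
  high <- tibble::tibble(
    group = "high",
    region = c("F", "C", "P", "O"),
    theta_beta = c(0.376, 0.395, 0.388, 0.373),
    alpha_beta = c(0.457, 0.462, 0.473, 0.457)
  )
  low <- if (plant == "observed") {
    tibble::tibble(
      group = "low",
      region = c("F", "C", "P", "O"),
      theta_beta = c(0.914, 0.805, 0.755, 0.846),
      alpha_beta = c(0.752, 0.812, 0.653, 0.772)
    )
  } else {
    dplyr::mutate(high,
      group = "low",
      alpha_beta = ifelse(.data$region %in% c("F", "C"),
                          c(F = 0.752, C = 0.812)[.data$region],
                          .data$alpha_beta))
  }
  dplyr::bind_rows(high, low)
}

#' Calibrate band tone amplitudes from ratio targets
#'
#' Converts per-group, per-region (theta/beta, alpha/beta) power-ratio
#' targets into sinusoid amplitudes. A tone of amplitude A carries power
#' A^2/2, so with the beta-band power fixed at `beta_power` the theta and
#' alpha amplitudes follow directly; pinning these two ratios also pins
#' (alpha+theta)/beta exactly, while theta/(alpha+theta) and
#' (alpha+theta)/(alpha+beta) are determined by algebra. Delta and gamma
#' tones are held at fixed small amplitudes since no ratio metric uses them.
#'
#' @param targets Tibble from [sa_ratio_targets()] (or same shape).
#' @param beta_power Beta-band tone power in uV^2 (default 20).
#' @param delta_amp,gamma_amp Fixed amplitudes in uV for the unused bands.
#' @return Tibble with columns `group`, `region`, `band`, `amplitude` (uV).
#' @export
calibrate_band_amplitudes <- function(targets = sa_ratio_targets(),
                                      beta_power = 20,
                                      delta_amp = 3, gamma_amp = 1.5) {
  stopifnot(all(c("group", "region", "theta_beta", "alpha_beta") %in% names(targets)))
  assert_scalar_number(beta_power, "beta_power", lower = 0)
  amp <- function(power) sqrt(2 * power)
  targets |>
    dplyr::rowwise() |>
    dplyr::reframe(
      group = .data$group, region = .data$region,
      band = c("delta", "theta", "alpha", "beta", "gamma"),
      amplitude = c(delta_amp,
                    amp(.data$theta_beta * beta_power),
                    amp(.data$alpha_beta * beta_power),
                    amp(beta_power),
                    gamma_amp)
    )
}

#' Specification of a synthetic EEG cohort
#'
#' Bundles everything the generator needs: sampling rate, duration, the
#' channel montage per region, calibrated per-group band tone amplitudes,
#' background pink noise, 50 Hz line interference, artifact injection rate,
#' and between-subject variability of band powers.
#'
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @param duration Recording length per subject in seconds (default 300).
#' @param regions Named integer vector of channels per region, e.g.
#'   `c(F = 2, C = 2, P = 2, O = 2)` (the montage itself is configuration,
#'   not a reproduction target).
#' @param band_amplitudes Tibble `group`/`region`/`band`/`amplitude` from
#'   [calibrate_band_amplitudes()].
#' @param pink_noise_sd Standard deviation of the 1/f background in uV.
#' @param line_noise_amp Amplitude of the 50 Hz line component in uV.
#' @param artifact_rate Artifact events per minute; each event is a
#'   half-sine pulse of 200-500 ms whose peak (250-400 uV) exceeds the
#'   200 uV rejection threshold.
#' @param subject_sd_log Between-subject SD of log band power, shared across
#'   regions (a subject's band power is a stable trait); default 0.15 puts
#'   the weakest planted frontal/central contrast near Cohen's d = 2.
#' @param region_sd_log Additional region-specific log-power jitter.
#' @param bands Band definition tibble, see [eeg_bands()].
#' @param tone_freqs Optional named vector of tone frequencies per band;
#'   defaults to band centres so analytic band-power bookkeeping is exact.
#' @return An object of class `synth_spec`.
#' @examples
#' spec <- synth_spec(duration = 20)
#' rec <- generate_recording(spec, group = "high", subject_id = "S01", seed = 1)
#' rec
#' @export
synth_spec <- function(sampling_rate = 256,
                       duration = 300,
                       regions = c(F = 2, C = 2, P = 2, O = 2),
                       band_amplitudes = calibrate_band_amplitudes(),
                       pink_noise_sd = 2,
                       line_noise_amp = 2,
                       artifact_rate = 0.5,
                       subject_sd_log = 0.15,
                       region_sd_log = 0.05,
                       bands = eeg_bands(),
                       tone_freqs = NULL) {
  assert_scalar_number(sampling_rate, "sampling_rate", lower = 1)
  assert_scalar_number(duration, "duration", lower = 0)
  assert_scalar_number(pink_noise_sd, "pink_noise_sd", lower = 0)
  assert_scalar_number(line_noise_amp, "line_noise_amp", lower = 0)
  assert_scalar_number(artifact_rate, "artifact_rate", lower = 0)
  bands <- eeg_bands(bands)
  if (sampling_rate <= 2 * max(bands$hi)) {
    stop("sampling_rate must exceed twice the highest band edge", call. = FALSE)
  }
  if (is.null(names(regions)) || any(!names(regions) %in% .regions)) {
    stop("regions must be a named vector with names among ",
         paste(.regions, collapse = ", "), call. = FALSE)
  }
  if (any(regions < 1)) stop("each region needs >= 1 channel", call. = FALSE)
  band_amplitudes <- tibble::as_tibble(band_amplitudes)
  stopifnot(all(c("group", "region", "band", "amplitude") %in% names(band_amplitudes)))
  if (any(band_amplitudes$amplitude < 0)) {
    stop("band amplitudes must be >= 0", call. = FALSE)
  }
  if (is.null(tone_freqs)) tone_freqs <- band_centers(bands)
  structure(
    list(sampling_rate = sampling_rate, duration = duration,
         regions = regions, band_amplitudes = band_amplitudes,
         pink_noise_sd = pink_noise_sd, line_noise_amp = line_noise_amp,
         artifact_rate = artifact_rate, subject_sd_log = subject_sd_log,
         region_sd_log = region_sd_log, bands = bands,
         tone_freqs = tone_freqs),
    class = "synth_spec"
  )
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec> ", x$duration, " s @ ", x$sampling_rate, " Hz; channels: ",
      paste(sprintf("%s=%d", names(x$regions), x$regions), collapse = " "),
      "\n  pink sd ", x$pink_noise_sd, " uV; 50 Hz amp ", x$line_noise_amp,
      " uV; artifacts ", x$artifact_rate, "/min\n", sep = "")
  invisible(x)
}

# 1/f-shaped noise: white noise whose positive-frequency amplitudes are
# scaled by 1/sqrt(f), rescaled to the requested SD.
pink_noise <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)   # two-sided frequency index
  f[1] <- 1             # keep DC finite (then recentred below)
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

half_sine_pulse <- function(n_samples, peak) {
  peak * sin(pi * seq_len(n_samples) / (n_samples + 1))
}

#' Generate one synthetic EEG recording
#'
#' Each channel is a sum of per-band sinusoids (frequency at the band
#' centre, random phase per channel), pink background noise, a 50 Hz line
#' component, and occasional high-amplitude half-sine artifact pulses. The
#' subject's band powers are drawn once (log-normal around the group's
#' calibrated level, shared across regions) so region-wise ratio metrics
#' converge to the group targets as the recording grows. Identical
#' `(spec, seed)` produce identical output.
#'
#' @param spec A [synth_spec()].
#' @param group `"high"` or `"low"` situation-awareness group.
#' @param subject_id Subject identifier string.
#' @param seed Integer seed for this subject.
#' @return An `eeg_recording`: list with `subject_id`, `group`,
#'   `sampling_rate`, `channels` (tibble `label`, `region`), `data`
#'   (samples x channels matrix, uV) and `artifact_log` (tibble with one row
#'   per injected pulse).
#' @export
generate_recording <- function(spec, group, subject_id, seed) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!group %in% c("high", "low")) {
    stop("group must be 'high' or 'low'", call. = FALSE)
  }
  if (spec$duration < 5) {
    stop("duration too short: need at least one 5 s epoch", call. = FALSE)
  }
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  amps <- dplyr::filter(spec$band_amplitudes, .data$group == !!group)
  missing_regions <- setdiff(names(spec$regions), unique(amps$region))
  if (length(missing_regions)) {
    stop("no band amplitudes for region(s): ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  }

  channels <- tibble::tibble(
    region = rep(names(spec$regions), spec$regions),
    label = unlist(lapply(seq_along(spec$regions), function(i) {
      paste0(names(spec$regions)[i], seq_len(spec$regions[i]))
    }), use.names = FALSE)
  )[, c("label", "region")]

  band_names <- spec$bands$band
  with_seed(seed, {
    # stable per-subject band traits, shared across regions
    subj_mult <- exp(stats::rnorm(length(band_names), 0, spec$subject_sd_log))
    names(subj_mult) <- band_names
    region_mult <- sapply(names(spec$regions), function(r) {
      exp(stats::rnorm(length(band_names), 0, spec$region_sd_log))
    })
    rownames(region_mult) <- band_names

    data <- matrix(0, n, nrow(channels))
    colnames(data) <- channels$label
    for (j in seq_len(nrow(channels))) {
      reg <- channels$region[j]
      a <- amps[match(band_names, amps$band), ]
      stopifnot(!anyNA(a$amplitude))
      x <- numeric(n)
      for (b in seq_along(band_names)) {
        bn <- band_names[b]
        # amplitude scales with sqrt of the power multiplier
        A <- a$amplitude[b] * sqrt(subj_mult[bn] * region_mult[bn, reg])
        if (A > 0) {
          phase <- stats::runif(1, 0, 2 * pi)
          x <- x + A * sin(2 * pi * spec$tone_freqs[bn] * t + phase)
        }
      }
      if (spec$pink_noise_sd > 0) x <- x + pink_noise(n, spec$pink_noise_sd)
      if (spec$line_noise_amp > 0) {
        x <- x + spec$line_noise_amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
      }
      data[, j] <- x
    }

    n_art <- stats::rpois(1, spec$artifact_rate * spec$duration / 60)
    artifact_log <- tibble::tibble(
      channel = character(0), start_s = numeric(0),
      end_s = numeric(0), peak = numeric(0)
    )
    if (n_art > 0) {
      for (i in seq_len(n_art)) {
        ch <- sample.int(nrow(channels), 1)
        dur <- stats::runif(1, 0.2, 0.5)
        peak <- stats::runif(1, 250, 400) * sample(c(-1, 1), 1)
        start <- stats::runif(1, 0, max(spec$duration - dur, 0))
        i0 <- floor(start * fs) + 1
        len <- max(round(dur * fs), 2)
        idx <- i0:min(i0 + len - 1, n)
        data[idx, ch] <- data[idx, ch] + half_sine_pulse(length(idx), peak)
        artifact_log <- dplyr::add_row(
          artifact_log, channel = channels$label[ch],
          start_s = (i0 - 1) / fs, end_s = (i0 - 1 + length(idx)) / fs,
          peak = peak)
      }
    }
    structure(
      list(subject_id = subject_id, group = group, sampling_rate = fs,
           channels = channels, data = data, artifact_log = artifact_log),
      class = "eeg_recording"
    )
  })
}

#' Generate a labelled synthetic cohort
#'
#' @param spec A [synth_spec()].
#' @param n_high,n_low Number of subjects per situation-awareness group
#'   (defaults 13 and 12).
#' @param seed Master seed; each subject's seed is derived deterministically
#'   from it and the subject's identity, so regenerating any one subject in
#'   isolation reproduces its series.
#' @return List of `eeg_recording` objects, high-SA subjects first.
#' @export
generate_cohort <- function(spec, n_high = 13, n_low = 12, seed = 1) {
  if (n_high < 1 || n_low < 1) stop("group sizes must be >= 1", call. = FALSE)
  recs <- c(
    lapply(seq_len(n_high), function(i) {
      id <- sprintf("high%02d", i)
      generate_recording(spec, "high", id, derive_seed(seed, "high", i))
    }),
    lapply(seq_len(n_low), function(i) {
      id <- sprintf("low%02d", i)
      generate_recording(spec, "low", id, derive_seed(seed, "low", i))
    })
  )
  recs
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id,
      if (!is.null(x$group)) paste0(" (", x$group, "-SA)"),
      ": ", nrow(x$data), " samples x ", ncol(x$data), " channels @ ",
      x$sampling_rate, " Hz, ", nrow(x$artifact_log), " artifacts\n", sep = "")
  invisible(x)
}

#' Recording as a wide tibble
#'
#' First column `time` in seconds, one column per channel named
#' `label@region`.
#'
#' @param x An `eeg_recording`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method tibble::as_tibble
as_tibble.eeg_recording <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$data))
  names(out) <- paste0(x$channels$label, "@", x$channels$region)
  dplyr::bind_cols(
    tibble::tibble(time = (seq_len(nrow(x$data)) - 1) / x$sampling_rate), out)
}
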