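#' Discrete Fourier transform of an amplitude series
#'
#' Computes `X(w) = sum_t x(t) exp(-i 2 pi w t / N)` for `w = 0 ... N-1`,
#' the forward DFT without normalisation (delegated to [stats::fft()], whose
#' convention matches exactly).
#'
#' @param series Numeric amplitude series (uV).
#' @return Complex vector of length `length(series)`.
#' @export
dft <- function(series) {
  if (length(series) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!is.numeric(series) || anyNA(series)) {
    stop("series must be numeric without NAs", call. = FALSE)
  }
  stats::fft(series)
}

#' Power spectral density of a series
#'
#' PSD per DFT bin under the normalisation
#' `S(w) = dt^2 / (N dt) * |X(w)|^2` with `dt = 1/fs`, i.e. `dt/N |X(w)|^2`
#' in uV^2 s. The full two-sided grid `w = 0 ... N-1` is returned; band
#' summaries use only positive frequencies up to Nyquist.
#'
#' @param series Numeric amplitude series (uV).
#' @param fs Sampling rate in Hz.
#' @return A `spectral_estimate` tibble with columns `frequency` (Hz) and
#'   `psd` (uV^2 s), and attributes `n_samples` and `dt`.
#' @examples
#' est <- psd(sin(2 * pi * 10 * (0:255) / 256), fs = 256)
#' est[which.max(est$psd), ]
#' @export
psd <- function(series, fs) {
  assert_scalar_number(fs, "fs", lower = 1e-12)
  X <- dft(series)
  n <- length(series)
  dt <- 1 / fs
  out <- tibble::tibble(
    frequency = (0:(n - 1)) * fs / n,
    psd = (dt / n) * Mod(X)^2
  )
  structure(out, n_samples = n, dt = dt,
            class = c("spectral_estimate", class(out)))
}

#' Band powers from a spectral estimate
#'
#' Sums PSD values over the DFT bins whose frequency falls inside each
#' band's half-open interval `[lo, hi)`. Only positive frequencies up to
#' Nyquist are counted (DC excluded), so each band's power is counted once.
#'
#' @param est A `spectral_estimate` from [psd()].
#' @param bands Band tibble from [eeg_bands()].
#' @return Tibble with columns `band` and `power`.
#' @export
band_powers <- function(est, bands = eeg_bands()) {
  bands <- eeg_bands(bands)
  n <- attr(est, "n_samples")
  dt <- attr(est, "dt")
  nyquist <- 1 / (2 * dt)
  if (any(bands$lo >= nyquist)) {
    stop("band lies above the Nyquist frequency", call. = FALSE)
  }
  f <- est$frequency
  keep <- f > 0 & f <= nyquist
  power <- vapply(seq_len(nrow(bands)), function(i) {
    sum(est$psd[keep & f >= bands$lo[i] & f < bands$hi[i]])
  }, numeric(1))
  tibble::tibble(band = bands$band, power = power)
}

#' Band-ratio metrics from band powers
#'
#' Computes the five frequency-combination metrics
#' theta/beta, alpha/beta, theta/(alpha+theta), (alpha+theta)/beta and
#' (alpha+theta)/(alpha+beta) from per-band powers.
#'
#' @param powers Tibble from [band_powers()] or named numeric vector with
#'   at least `theta`, `alpha` and `beta` entries.
#' @return Tibble with columns `metric` (canonical order, see
#'   [ratio_metric_names()]) and `value`.
#' @export
ratio_metrics <- function(powers) {
  p <- if (is.data.frame(powers)) {
    stats::setNames(powers$power, powers$band)
  } else powers
  need <- c("theta", "alpha", "beta")
  if (!all(need %in% names(p))) {
    stop("powers must include theta, alpha and beta", call. = FALSE)
  }
  if (any(p < 0, na.rm = TRUE)) stop("powers must be >= 0", call. = FALSE)
  th <- unname(p["theta"]); al <- unname(p["alpha"]); be <- unname(p["beta"])
  if (be == 0 || al + be == 0 || al + th == 0) {
    stop("degenerate band powers: zero denominator in a ratio metric",
         call. = FALSE)
  }
  tibble::tibble(
    metric = .metric_order,
    value = c(th / be, al / be, th / (al + th), (al + th) / be,
              (al + th) / (al + be))
  )
}

# RBJ-style second-order IIR notch coefficients (b, a) at f0 with the given
# -3 dB bandwidth.
notch_coefficients <- function(f0, fs, bandwidth = 1) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) * sinh(log(2) / 2 * (bandwidth / f0) * w0 / sin(w0))
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Remove power-line interference
#'
#' Applies a zero-phase (forward-backward) second-order IIR notch centred at
#' `f0` to every channel. The narrow notch removes the line component while
#' leaving passband power essentially untouched (<1 dB away from the notch).
#'
#' @param rec An `eeg_recording`.
#' @param f0 Line frequency in Hz (default 50).
#' @param bandwidth Notch -3 dB bandwidth in Hz (default 2; wide enough
#'   that filter transients decay within a second, narrow enough to leave
#'   the gamma band untouched).
#' @return The recording with filtered data.
#' @export
remove_line_noise <- function(rec, f0 = 50, bandwidth = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (f0 >= fs / 2) stop("f0 must lie below the Nyquist frequency", call. = FALSE)
  co <- notch_coefficients(f0, fs, bandwidth)
  filt <- signal::Arma(b = co$b, a = co$a)
  rec$data <- apply(rec$data, 2, function(x) signal::filtfilt(filt, x))
  rec
}

#' Flag amplitude artifacts
#'
#' Marks every sample whose absolute amplitude on any channel exceeds the
#' threshold, then dilates each mark to the full non-overlapping 5 s epoch
#' containing it; flagged epochs are excluded from feature extraction.
#'
#' @param rec An `eeg_recording`.
#' @param threshold Rejection threshold in uV (default 200).
#' @param epoch Epoch length in seconds used for dilation (default 5).
#' @return Logical per-sample mask (`TRUE` = artifact epoch), with the
#'   1-based indices of flagged epochs in attribute `flagged_epochs`.
#' @export
flag_artifacts <- function(rec, threshold = 200, epoch = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_number(threshold, "threshold", lower = 1e-12)
  n <- nrow(rec$data)
  hit <- rowSums(abs(rec$data) > threshold) > 0
  samples_per_epoch <- round(epoch * rec$sampling_rate)
  epoch_of <- (seq_len(n) - 1) %/% samples_per_epoch + 1
  flagged <- sort(unique(epoch_of[hit]))
  mask <- epoch_of %in% flagged
  attr(mask, "flagged_epochs") <- flagged
  mask
}

#' Export an artifact mask as intervals
#'
#' Collapses a per-sample mask to a BED-like interval table
#' (`subject`, `start_s`, `end_s`).
#'
#' @param rec The recording the mask belongs to.
#' @param mask Logical mask from [flag_artifacts()].
#' @return Tibble with one row per contiguous flagged interval.
#' @export
mask_intervals <- function(rec, mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(
    subject = rec$subject_id,
    start_s = (starts[keep] - 1) / rec$sampling_rate,
    end_s = ends[keep] / rec$sampling_rate
  )
}
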