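#' Canonical EEG frequency bands
#'
#' Returns the five canonical EEG bands as contiguous half-open intervals
#' `[lo, hi)` in Hz: delta `[1, 5)`, theta `[5, 9)`, alpha `[9, 15)`,
#' beta `[15, 31)`, gamma `[31, 60)`. The conventional integer band edges
#' (1-4, 5-8, 9-14, 15-30, 31-59 Hz) leave 1 Hz gaps between bands; on the
#' 0.2 Hz DFT grid of a 5 s epoch those gaps would silently drop bins, so
#' each band is widened to the next band's lower edge and treated as
#' half-open.
#'
#' @param bands Optional tibble with columns `band`, `lo`, `hi` to validate
#'   and use instead of the defaults.
#' @return A tibble with columns `band` (ordered factor level names
#'   `delta`, `theta`, `alpha`, `beta`, `gamma`), `lo` and `hi` (Hz).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- tibble::tibble(
      band = c("delta", "theta", "alpha", "beta", "gamma"),
      lo   = c(1, 5, 9, 15, 31),
      hi   = c(5, 9, 15, 31, 60)
    )
  }
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("band", "lo", "hi") %in% names(bands)))
  if (any(bands$lo >= bands$hi)) {
    stop("each band must satisfy lo < hi", call. = FALSE)
  }
  ord <- order(bands$lo)
  bands <- bands[ord, ]
  if (nrow(bands) > 1 && any(bands$hi[-nrow(bands)] > bands$lo[-1])) {
    stop("bands must be non-overlapping", call. = FALSE)
  }
  bands
}

#' Band-center frequencies
#'
#' Midpoint of each band interval, used as the default placement for the
#' synthetic generator's band tones.
#'
#' @param bands A band tibble from [eeg_bands()].
#' @return Named numeric vector of centre frequencies in Hz.
#' @keywords internal
band_centers <- function(bands = eeg_bands()) {
  stats::setNames((bands$lo + bands$hi) / 2, bands$band)
}

# Canonical metric order; indices within a selected subset follow this order,
# which reproduces the conventional mean/median feature naming
# (metric 1 = alpha/beta, 2 = theta/(alpha+theta), 3 = (alpha+theta)/beta
# when exactly those three are selected).
.metric_order <- c(
  "theta_beta", "alpha_beta", "theta_alphatheta",
  "alphatheta_beta", "alphatheta_alphabeta"
)

.metric_labels <- c(
  theta_beta           = "θ/β",
  alpha_beta           = "α/β",
  theta_alphatheta     = "θ/(α+θ)",
  alphatheta_beta      = "(α+θ)/β",
  alphatheta_alphabeta = "(α+θ)/(α+β)"
)

#' Names of the five band-ratio metrics
#'
#' The five frequency-combination metrics used throughout the package, in
#' canonical order: theta/beta, alpha/beta, theta/(alpha+theta),
#' (alpha+theta)/beta and (alpha+theta)/(alpha+beta).
#'
#' @param labels If `TRUE`, return display labels (Greek) instead of the
#'   machine-readable names.
#' @return Character vector of length five.
#' @export
ratio_metric_names <- function(labels = FALSE) {
  if (labels) unname(.metric_labels[.metric_order]) else .metric_order
}

.regions <- c("F", "C", "P", "T", "O")
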