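#' Read and write recordings as CSV
#'
#' The interchange format is a plain CSV dialect: first column `time` in
#' seconds, then one column per channel with header `label@region`
#' (e.g. `F1@F`). Group and subject metadata travel in comment header lines
#' beginning with `#`.
#'
#' @param rec An `eeg_recording`.
#' @param path File path.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject_id=%s", rec$subject_id), con)
  writeLines(sprintf("# group=%s", rec$group %||% "NA"), con)
  writeLines(sprintf("# sampling_rate=%s", format(rec$sampling_rate)), con)
  tb <- tibble::as_tibble(rec)
  utils::write.csv(tb, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  header <- readLines(path, n = 10)
  meta <- header[startsWith(header, "#")]
  get_meta <- function(key) {
    line <- grep(paste0("^# ", key, "="), meta, value = TRUE)
    if (!length(line)) return(NA_character_)
    sub(paste0("^# ", key, "="), "", line[1])
  }
  tb <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  chan_cols <- setdiff(names(tb), "time")
  if (!all(grepl("@", chan_cols, fixed = TRUE))) {
    stop("channel headers must be of the form label@region", call. = FALSE)
  }
  parts <- strsplit(chan_cols, "@", fixed = TRUE)
  channels <- tibble::tibble(
    label = vapply(parts, `[[`, "", 1),
    region = vapply(parts, `[[`, "", 2)
  )
  fs <- suppressWarnings(as.numeric(get_meta("sampling_rate")))
  if (!is.finite(fs)) {
    dt <- diff(tb$time[1:2])
    fs <- round(1 / dt)
  }
  data <- as.matrix(tb[chan_cols])
  colnames(data) <- channels$label
  grp <- get_meta("group")
  structure(
    list(subject_id = get_meta("subject_id"),
         group = if (identical(grp, "NA")) NULL else grp,
         sampling_rate = fs, channels = channels, data = data,
         artifact_log = tibble::tibble(channel = character(0),
                                       start_s = numeric(0),
                                       end_s = numeric(0),
                                       peak = numeric(0))),
    class = "eeg_recording"
  )
}

#' Read or write a generator specification as YAML
#'
#' @param spec A [synth_spec()].
#' @param path File path.
#' @export
write_synth_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synth_spec"))
  obj <- list(
    sampling_rate = spec$sampling_rate, duration = spec$duration,
    regions = as.list(spec$regions),
    band_amplitudes = lapply(seq_len(nrow(spec$band_amplitudes)), function(i) {
      as.list(spec$band_amplitudes[i, ])
    }),
    pink_noise_sd = spec$pink_noise_sd, line_noise_amp = spec$line_noise_amp,
    artifact_rate = spec$artifact_rate, subject_sd_log = spec$subject_sd_log,
    region_sd_log = spec$region_sd_log,
    bands = lapply(seq_len(nrow(spec$bands)), function(i) as.list(spec$bands[i, ]))
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_synth_spec
#' @export
read_synth_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  synth_spec(
    sampling_rate = obj$sampling_rate, duration = obj$duration,
    regions = unlist(obj$regions),
    band_amplitudes = dplyr::bind_rows(lapply(obj$band_amplitudes, tibble::as_tibble)),
    pink_noise_sd = obj$pink_noise_sd, line_noise_amp = obj$line_noise_amp,
    artifact_rate = obj$artifact_rate, subject_sd_log = obj$subject_sd_log,
    region_sd_log = obj$region_sd_log,
    bands = dplyr::bind_rows(lapply(obj$bands, tibble::as_tibble))
  )
}
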