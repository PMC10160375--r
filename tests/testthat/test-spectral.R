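test_that("dft matches the direct-sum definition", {
  # frozen closed-form cases
  expect_equal(dft(rep(3, 8)), c(24 + 0i, rep(0 + 0i, 7)), tolerance = 1e-12)
  x <- cos(2 * pi * (0:7) / 8)
  X <- dft(x)
  expect_equal(Mod(X[c(2, 8)]), c(4, 4), tolerance = 1e-12)
  expect_equal(Mod(X[-c(2, 8)]), rep(0, 6), tolerance = 1e-12)
  # linearity
  set.seed(1)
  a <- rnorm(32); b <- rnorm(32)
  expect_equal(dft(a + b), dft(a) + dft(b), tolerance = 1e-9)
  expect_error(dft(numeric(0)), "2 samples")
})

test_that("psd implements the stated normalisation", {
  # cos(2 pi t / 8), N = 8, fs = 256: S(1) = (1/256)/8 * 16 = 0.0078125
  x <- cos(2 * pi * (0:7) / 8)
  est <- psd(x, fs = 256)
  expect_equal(est$psd[2], 0.0078125, tolerance = 1e-12)
  expect_equal(psd(numeric(16), 256)$psd, rep(0, 16))
  set.seed(2)
  y <- rnorm(64)
  expect_equal(psd(2 * y, 128)$psd, 4 * psd(y, 128)$psd, tolerance = 1e-9)
})

test_that("Parseval-style identity holds under the psd normalisation", {
  set.seed(3)
  for (n in c(16, 100, 256)) {
    x <- rnorm(n)
    fs <- 256
    est <- psd(x, fs)
    expect_equal(sum(est$psd), (1 / fs) * sum(x^2), tolerance = 1e-9)
  }
})

test_that("band powers assign tones to their bands and reject bad bands", {
  fs <- 256
  t <- (0:(5 * fs - 1)) / fs
  est <- psd(sin(2 * pi * 10 * t), fs)
  bp <- band_powers(est)
  expect_gt(bp$power[bp$band == "alpha"] / sum(bp$power), 0.99)
  expect_equal(band_powers(psd(numeric(64), fs))$power, rep(0, 5))
  for (f0 in c(6, 3)) {
    bp <- band_powers(psd(sin(2 * pi * f0 * t), fs))
    expect_equal(bp$band[which.max(bp$power)],
                 if (f0 == 6) "theta" else "delta")
  }
  bad <- eeg_bands()
  bad$lo[5] <- 200; bad$hi[5] <- 300
  expect_error(band_powers(psd(rnorm(64), 64), bad), "Nyquist")
})

test_that("ratio metrics compute the five ratios exactly", {
  p <- c(theta = 0.2, alpha = 0.4, beta = 0.5)
  m <- ratio_metrics(p)
  expect_equal(m$value, c(0.4, 0.8, 1 / 3, 1.2, 2 / 3), tolerance = 1e-12)
  eq <- ratio_metrics(c(theta = 2, alpha = 2, beta = 2))
  expect_equal(eq$value, c(1, 1, 0.5, 2, 1), tolerance = 1e-12)
  expect_error(ratio_metrics(c(theta = 1, alpha = 1, beta = 0)), "degenerate")
  # theta/(alpha+theta) bounded in [0, 1] for random powers
  set.seed(4)
  for (i in 1:20) {
    v <- ratio_metrics(c(theta = runif(1), alpha = runif(1),
                         beta = runif(1, 0.1)))
    expect_true(v$value[3] >= 0 && v$value[3] <= 1)
    expect_true(all(v$value >= 0))
  }
})

test_that("the notch removes 50 Hz and leaves the passband alone", {
  fs <- 256
  t <- (0:(4 * fs - 1)) / fs
  mk <- function(x) {
    structure(list(subject_id = "S", group = NULL, sampling_rate = fs,
                   channels = tibble::tibble(label = "F1", region = "F"),
                   data = matrix(x, ncol = 1,
                                 dimnames = list(NULL, "F1")),
                   artifact_log = tibble::tibble()),
              class = "eeg_recording")
  }
  tone50 <- mk(sin(2 * pi * 50 * t))
  out <- remove_line_noise(tone50)
  mid <- (fs + 1):(3 * fs)   # steady state, away from filter edge transients
  at50 <- function(r) {
    est <- psd(r$data[mid, 1], fs)
    sum(est$psd[abs(est$frequency - 50) <= 0.5])
  }
  expect_lt(at50(out) / at50(tone50), 1e-4)   # residual amplitude <= 1%
  tone10 <- mk(sin(2 * pi * 10 * t))
  out10 <- remove_line_noise(tone10)
  p10 <- function(r) {
    est <- psd(r$data[mid, 1], fs)
    sum(est$psd[abs(est$frequency - 10) <= 0.5])
  }
  expect_lt(abs(10 * log10(p10(out10) / p10(tone10))), 1)
  z <- mk(numeric(length(t)))
  expect_equal(remove_line_noise(z)$data, z$data)
  expect_error(remove_line_noise(tone50, f0 = 200), "Nyquist")
})

test_that("artifact flagging dilates to the containing 5 s epoch", {
  fs <- 256
  x <- matrix(0, 20 * fs, 1, dimnames = list(NULL, "F1"))
  x[7 * fs + 3, 1] <- 250    # epoch 2 (5-10 s)
  rec <- structure(list(subject_id = "S", group = NULL, sampling_rate = fs,
                        channels = tibble::tibble(label = "F1", region = "F"),
                        data = x, artifact_log = tibble::tibble()),
                   class = "eeg_recording")
  mask <- flag_artifacts(rec)
  expect_equal(attr(mask, "flagged_epochs"), 2)
  expect_true(all(mask[(5 * fs + 1):(10 * fs)]))
  expect_false(any(mask[1:(5 * fs)]))
  rec$data[] <- 100
  expect_equal(sum(flag_artifacts(rec)), 0)
  iv <- mask_intervals(rec, mask)
  expect_equal(iv$start_s, 5)
  expect_equal(iv$end_s, 10)
})

test_that("every injected artifact's epoch is flagged", {
  spec <- synth_spec(duration = 60, artifact_rate = 6)
  rec <- generate_recording(spec, "low", "S1", seed = 8)
  mask <- flag_artifacts(rec)
  inj_epochs <- unique(floor(rec$artifact_log$start_s / 5) + 1)
  also <- unique(floor((rec$artifact_log$end_s - 1e-9) / 5) + 1)
  expect_true(all(union(inj_epochs, also) %in% attr(mask, "flagged_epochs")))
})

test_that("feature extraction yields the documented table shape", {
  # integer tone frequencies land on exact 1 s DFT bins, so every
  # sub-epoch of the stationary signal is spectrally identical
  spec <- quiet_spec(duration = 60,
                     tone_freqs = c(delta = 3, theta = 7, alpha = 12,
                                    beta = 23, gamma = 45))
  rec <- generate_recording(spec, "high", "S1", seed = 6)
  ft0 <- extract_features(rec, overlap = 0)
  expect_equal(nrow(ft0), 12)            # floor(60 / 5)
  fn <- feature_names()
  expect_equal(setdiff(names(ft0), c("subject_id", "group", "epoch_index",
                                     "window_start_s")),
               fn$feature)
  expect_equal(length(fn$feature), 12)
  # stationary tone signal: every sub-epoch identical, so mean == median
  for (f in fn$feature) expect_equal(ft0[[f]], ft0[[f]], tolerance = 1e-10)
  ftM <- ft0[fn$feature[fn$stat == "M"]]
  ftP <- ft0[fn$feature[fn$stat == "P"]]
  expect_equal(unname(as.matrix(ftM)), unname(as.matrix(ftP)),
               tolerance = 1e-8)
})

test_that("feature extraction is invariant to channel order within a region", {
  spec <- synth_spec(duration = 20)
  rec <- generate_recording(spec, "high", "S1", seed = 7)
  swapped <- rec
  ford <- which(rec$channels$region == "F")
  swapped$data[, ford] <- rec$data[, rev(ford)]
  f1 <- extract_features(rec)
  f2 <- extract_features(swapped)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("fully flagged recordings are rejected", {
  spec <- synth_spec(duration = 10, artifact_rate = 0)
  rec <- generate_recording(spec, "high", "S1", seed = 9)
  rec$data[] <- 500
  expect_error(extract_features(rec), "flagged")
})
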