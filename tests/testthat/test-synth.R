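test_that("a pure alpha tone concentrates its power in the alpha band", {
  amps <- calibrate_band_amplitudes()
  amps$amplitude <- ifelse(amps$band == "alpha", 10, 0)
  spec <- quiet_spec(duration = 10, band_amplitudes = amps,
                     tone_freqs = c(delta = 3, theta = 7, alpha = 10,
                                    beta = 23, gamma = 45))
  rec <- generate_recording(spec, "high", "S1", seed = 1)
  est <- psd(rec$data[1:2560, 1], fs = spec$sampling_rate)
  bp <- band_powers(est)
  expect_gt(bp$power[bp$band == "alpha"] / sum(bp$power), 0.99)
})

test_that("generation is a pure function of spec and seed", {
  spec <- synth_spec(duration = 6, artifact_rate = 5)
  r1 <- generate_recording(spec, "low", "S1", seed = 9)
  r2 <- generate_recording(spec, "low", "S1", seed = 9)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$artifact_log, r2$artifact_log)
  r3 <- generate_recording(spec, "low", "S1", seed = 10)
  expect_false(identical(r1$data, r3$data))
})

test_that("noise-free ratio metrics match the calibrated targets", {
  # analytic: a tone of amplitude A has power A^2/2, so the configured
  # (theta/beta, alpha/beta) pair is hit exactly and (alpha+theta)/beta
  # follows; verified on a 10-minute noiseless recording
  spec <- quiet_spec(duration = 600)
  rec <- generate_recording(spec, "high", "S1", seed = 2)
  sv <- subject_metric_means(list(rec), line_filter = FALSE,
                             regions = "F")
  targets <- dplyr::filter(sa_ratio_targets(), group == "high", region == "F")
  ab <- sv$value[sv$metric == "alpha_beta"]
  tb <- sv$value[sv$metric == "theta_beta"]
  atb <- sv$value[sv$metric == "alphatheta_beta"]
  expect_lt(abs(ab - 0.457), 0.05)
  expect_lt(abs(ab / targets$alpha_beta - 1), 0.05)
  expect_lt(abs(tb / targets$theta_beta - 1), 0.05)
  expect_lt(abs(atb / (targets$theta_beta + targets$alpha_beta) - 1), 0.05)
})

test_that("cohorts have the requested sizes, labels and stable per-subject streams", {
  spec <- synth_spec(duration = 6)
  cohort <- generate_cohort(spec, n_high = 13, n_low = 12, seed = 3)
  expect_length(cohort, 25)
  expect_equal(sum(vapply(cohort, function(r) r$group, "") == "high"), 13)
  # regenerating one subject in isolation reproduces its series
  r7 <- generate_recording(spec, "high", "high07",
                           seed = eegsa:::derive_seed(3, "high", 7))
  expect_identical(cohort[[7]]$data, r7$data)
  small <- generate_cohort(spec, 1, 1, seed = 3)
  expect_false(identical(small[[1]]$data, small[[2]]$data))
  expect_error(generate_cohort(spec, 0, 5), "group sizes")
})

test_that("artifact injection is reproducible and exceeds the rejection threshold", {
  spec <- synth_spec(duration = 60, artifact_rate = 6)
  rec <- generate_recording(spec, "low", "S1", seed = 4)
  expect_gt(nrow(rec$artifact_log), 0)
  expect_true(all(abs(rec$artifact_log$peak) > 200))
  rec2 <- generate_recording(spec, "low", "S1", seed = 4)
  expect_identical(rec$artifact_log, rec2$artifact_log)
})

test_that("degenerate generation requests error", {
  expect_error(generate_recording(synth_spec(duration = 3), "high", "S", 1),
               "5 s epoch")
  expect_error(generate_recording(synth_spec(duration = 6), "medium", "S", 1),
               "group")
  expect_error(synth_spec(regions = c(Q = 2)), "region")
  expect_error(synth_spec(sampling_rate = 100), "Nyquist|band edge")
})

test_that("recordings round-trip through the CSV dialect", {
  spec <- synth_spec(duration = 6)
  rec <- generate_recording(spec, "high", "S1", seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(back$subject_id, "S1")
  expect_equal(back$group, "high")
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_identical(back$channels, rec$channels)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
})

test_that("generator specs round-trip through YAML", {
  spec <- synth_spec(duration = 8, pink_noise_sd = 1.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_spec(spec, path)
  back <- read_synth_spec(path)
  expect_equal(back$duration, 8)
  expect_equal(back$pink_noise_sd, 1.5)
  expect_equal(back$band_amplitudes, spec$band_amplitudes)
  r1 <- generate_recording(spec, "high", "S1", 1)
  r2 <- generate_recording(back, "high", "S1", 1)
  expect_equal(r1$data, r2$data, tolerance = 1e-9)
})
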