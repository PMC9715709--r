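test_that("gestational-age stratification matches the study groups", {
  expect_equal(as.character(ga_group_of(c(24, 28.9, 29, 33.9, 37, 41))),
               c("early", "early", "mid", "mid", "term", "term"))
  expect_error(ga_group_of(35), "outside the study design")
})

test_that("same spec and seed give bit-identical recordings", {
  sp <- subject_spec("a", 27, seed = 11)
  p <- epoch_params()
  r1 <- simulate_recording(sp, p)
  r2 <- simulate_recording(sp, p)
  expect_identical(r1$recording$voltage_uV, r2$recording$voltage_uV)
  expect_identical(r1$truth$minute_labels, r2$truth$minute_labels)
  r3 <- simulate_recording(subject_spec("a", 27, seed = 12), p)
  expect_false(identical(r1$recording$voltage_uV, r3$recording$voltage_uV))
})

test_that("a degenerate all-normogastria chain emits a pure in-band tone", {
  p <- sim_params(fs_raw = 16, duration_min = 30, feed_times = list(),
                  occupancy = c(0, 1, 0), noise_sd = 0, artifact_rate = 0)
  out <- simulate_recording(subject_spec("s", 30, 5), p)
  expect_true(all(out$truth$minute_labels$band == "normo"))
  expect_true(all(out$truth$minute_labels$freq_cpm >= 2 &
                    out$truth$minute_labels$freq_cpm < 4))
  # spectral check: all power at the drawn frequencies, inside normogastria
  ps <- welch_psd(preprocess_egg(out$recording), window_s = 240)
  peak <- ps$freq_cpm[which.max(ps$psd)]
  expect_gte(peak, 2)
  expect_lt(peak, 4)
})

test_that("signal length and ground-truth bookkeeping are consistent", {
  p <- epoch_params()
  out <- simulate_recording(subject_spec("s", 25, 3), p)
  expect_equal(nrow(out$recording), 96 * 60 * 16)
  expect_equal(nrow(out$truth$minute_labels), 96)
  w <- segment_feeds(single_feed_tbl(), 96, allow_single_feed = TRUE)
  tp <- true_percent_time(out$truth, w)
  sums <- tapply(tp$pct, tp$window_label, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 100) < 1e-9))
})

test_that("zero-noise per-minute band-limited RMS power matches the true labels", {
  # independent oracle: band-limited RMS via signal::butter directly
  p <- sim_params(fs_raw = 16, duration_min = 60, feed_times = list(),
                  noise_sd = 0, artifact_rate = 0)
  out <- simulate_recording(subject_spec("s", 28, 21), p)
  x <- out$recording$voltage_uV
  fs <- 16
  b <- gastric_bands()
  rms_min <- sapply(seq_len(nrow(b)), function(i) {
    filt <- signal::butter(2, c(b$lo_hz[i], b$hi_hz[i]) * 2 / fs, type = "pass")
    y <- signal::filtfilt(filt, x)
    sqrt(colMeans(matrix(y^2, nrow = 60 * fs)))
  })
  got <- band_levels()[apply(rms_min, 1, which.max)]
  agree <- mean(got == as.character(out$truth$minute_labels$band))
  expect_gte(agree, 0.9)   # filter roll-off blurs dwell switches slightly
})

test_that("long-run minute fractions converge to the stationary occupancy", {
  p <- sim_params(fs_raw = 4, duration_min = 360, feed_times = list(),
                  occupancy = c(1, 1, 1) / 3, mean_dwell_min = 5,
                  noise_sd = 0, artifact_rate = 0)
  labs <- unlist(lapply(1:50, function(s) {
    as.character(simulate_recording(subject_spec("s", 30, s), p)$truth$minute_labels$band)
  }))
  n <- length(labs)
  se <- sqrt((1 / 3) * (2 / 3) / (n / 5))   # dwell ~5 min => ~n/5 independent draws
  for (bl in band_levels()) {
    expect_lt(abs(mean(labs == bl) - 1 / 3), 3 * se)
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_params(feed_times = list(c(10, 30), c(20, 30))), "overlap")
  expect_error(sim_params(duration_min = 50, feed_times = list(c(30, 30))),
               "within the recording")
  expect_error(sim_params(duration_min = 5), "at least 10")
  expect_error(sim_params(fs_raw = 2), "at least 4")
  expect_error(sim_params(occupancy = c(0.5, 0.6, 0.2)), "summing to 1")
})

test_that("default cohort reproduces the study head-count and strata", {
  coh <- simulate_cohort(c(25, 22, 4), epoch_params(), master_seed = 1,
                         keep_recordings = FALSE)
  expect_equal(nrow(coh$subjects), 51)
  expect_equal(as.integer(table(coh$subjects$ga_group)), c(25, 22, 4))
  one <- simulate_cohort(c(0, 0, 1), epoch_params(), master_seed = 2,
                         keep_recordings = FALSE)
  expect_equal(nrow(one$subjects), 1)
  expect_gte(one$subjects$ga_weeks, 37)
  # reproducible from the master seed
  coh2 <- simulate_cohort(c(25, 22, 4), epoch_params(), master_seed = 1,
                          keep_recordings = FALSE)
  expect_identical(coh$subjects, coh2$subjects)
})

test_that("occupancy trend is strictly increasing in normogastria across groups", {
  occ <- sapply(c(26, 31.5, 39), ga_occupancy)
  expect_true(all(diff(occ["normo", ]) > 0))
  expect_true(all(abs(colSums(occ) - 1) < 1e-12))
})
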