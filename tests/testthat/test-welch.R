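test_that("a 240-s window gives 1/240 Hz resolution and the identity holds", {
  rec <- tone_rec(3, minutes = 30)
  ps <- welch_psd(rec, window_s = 240, overlap_s = 120)
  expect_equal(attr(ps, "resolution_hz") * attr(ps, "window_s"), 1)
  expect_equal(attr(ps, "resolution_hz"), 1 / 240)
  expect_equal(round(attr(ps, "resolution_hz"), 3), 0.004)
})

test_that("a unit tone's density integrates to its power (0.5)", {
  for (f in c(1.2, 3, 6.5)) {
    ps <- welch_psd(tone_rec(f, minutes = 30), window_s = 240)
    expect_lt(abs(sum(ps$psd) * attr(ps, "resolution_hz") - 0.5), 0.025)
    peak <- ps$freq_hz[which.max(ps$psd)]
    expect_equal(as.character(band_of_cpm(peak * 60)),
                 as.character(band_of_cpm(f)))
  }
})

test_that("white-noise density is flat at sigma^2/(fs/2)", {
  set.seed(42)
  fs <- 4; sigma <- 3
  ratios <- replicate(20, {
    ps <- welch_psd(egg_recording(rnorm(fs * 1200, sd = sigma), fs),
                    window_s = 240)
    mean(ps$psd) / (sigma^2 / (fs / 2))
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("single-window Welch equals a directly computed periodogram", {
  set.seed(7)
  fs <- 4
  x <- rnorm(fs * 200)
  rec <- egg_recording(x, fs)
  expect_warning(ps <- welch_psd(rec, window_s = 240), "single full-length")
  # independent oracle: rectangular-equivalent periodogram with Hamming taper
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(n) / (n + 1))
  X <- fft(x * w)[seq_len(n %/% 2 + 1)]
  p <- Mod(X)^2 / (fs * sum(w^2))
  dbl <- rep(2, length(p)); dbl[1] <- 1; if (n %% 2 == 0) dbl[length(p)] <- 1
  expect_equal(ps$psd, p * dbl, tolerance = 1e-12)
})

test_that("band means follow indicator spectra and flat spectra", {
  b <- gastric_bands()
  freqs <- seq(0, 0.2, by = 1 / 240)
  flat <- tibble::tibble(freq_hz = freqs, psd = rep(2.5, length(freqs)))
  expect_equal(band_mean_psd(flat)$mpsd, rep(2.5, 3))
  ind <- tibble::tibble(freq_hz = freqs,
                        psd = as.numeric(freqs >= b$lo_hz[2] & freqs < b$hi_hz[2]))
  expect_equal(band_mean_psd(ind)$mpsd, c(0, 1, 0))
})

test_that("a 3-cpm tone concentrates its band mean in normogastria", {
  ps <- welch_psd(tone_rec(3, minutes = 30), window_s = 240)
  m <- band_mean_psd(ps)
  expect_gt(m$mpsd[m$band == "normo"], 10 * m$mpsd[m$band == "brady"])
  expect_gt(m$mpsd[m$band == "normo"], 10 * m$mpsd[m$band == "tachy"])
})

test_that("doubling amplitude quadruples every band mean", {
  m1 <- band_mean_psd(welch_psd(tone_rec(3, minutes = 20, amp = 1), window_s = 240))
  m2 <- band_mean_psd(welch_psd(tone_rec(3, minutes = 20, amp = 2), window_s = 240))
  expect_equal(m2$mpsd[2] / m1$mpsd[2], 4, tolerance = 1e-6)
})

test_that("band partition: bin-weighted band means recompose the gastric mean", {
  set.seed(3)
  ps <- welch_psd(egg_recording(rnorm(4 * 1800), fs = 4), window_s = 240)
  b <- gastric_bands()
  m <- band_mean_psd(ps)
  nb <- sapply(seq_len(3), function(i) {
    sum(ps$freq_hz >= b$lo_hz[i] & ps$freq_hz < b$hi_hz[i])
  })
  sel <- ps$freq_hz >= b$lo_hz[1] & ps$freq_hz < b$hi_hz[3]
  expect_equal(sum(m$mpsd * nb) / sum(nb), mean(ps$psd[sel]), tolerance = 1e-12)
})

test_that("too-short or empty segments are rejected informatively", {
  expect_error(welch_psd(egg_recording(rnorm(100), fs = 4)), "too short")
  rec <- egg_recording(rnorm(4 * 100), fs = 4)
  expect_error(welch_psd(rec, min_s = 125), "125")
})

test_that("phase averaging combines the two feeding epochs per band", {
  pw <- tibble::tibble(
    window_label = rep(c("pre1", "pre2"), each = 3),
    band = factor(rep(band_levels(), 2), levels = band_levels()),
    mpsd = c(2, 4, 6, 4, 4, 2)
  )
  out <- phase_average(pw)
  expect_equal(out$mpsd, c(3, 4, 4))
  expect_true(all(out$n_windows == 2))
  # a lone window errors unless explicitly allowed, then passes through
  lone <- pw[pw$window_label == "pre1", ]
  expect_error(phase_average(lone), "single window")
  out1 <- phase_average(lone, allow_single = TRUE)
  expect_equal(out1$mpsd, c(2, 4, 6))
  expect_true(all(out1$n_windows == 1))
})
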