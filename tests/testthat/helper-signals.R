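# shared fixture builders: pure tones and small-scale simulator settings

tone_rec <- function(f_cpm, minutes = 30, fs = 4, amp = 1, subject_id = "tone") {
  t <- seq(0, minutes * 60 - 1 / fs, by = 1 / fs)
  egg_recording(amp * sin(2 * pi * (f_cpm / 60) * t), fs = fs,
                subject_id = subject_id)
}

# 96-min single-feed epoch at a reduced raw rate (signal content < 0.25 Hz,
# so the analysis chain is unchanged)
epoch_params <- function(...) {
  sim_params(fs_raw = 16, duration_min = 96, feed_times = list(c(30, 30)), ...)
}

# 216-min two-feed schedule matching the canonical worked segmentation
two_feed_params <- function(...) {
  sim_params(fs_raw = 16, duration_min = 216,
             feed_times = list(c(30, 30), c(156, 30)), ...)
}

# fast options for smoke runs on short windows
quick_opts <- function(...) {
  egg_options(welch_window_s = 120, welch_overlap_s = 60, ...)
}

single_feed_tbl <- function() tibble::tibble(start_min = 30, end_min = 60)
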