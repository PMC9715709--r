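# Zero-phase IIR filtering.
#
# signal::filtfilt() applies the two passes with zero initial state, which
# leaves sizeable start/end transients for filters with long time constants
# (a 1 Hz low-pass at 500 Hz, or the gastric band-pass whose lower edge is
# 0.0083 Hz). We instead mirror-pad the signal (odd reflection about the end
# points) and start each pass from the steady state of a constant input equal
# to the first padded sample, so a DC input passes through exactly and edge
# transients are confined to the discarded padding.

filter_steady <- function(b, a, x) {
  nf <- max(length(a), length(b)) - 1L
  g <- sum(b) / sum(a)  # DC gain
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], nf),
                            init.y = rep(g * x[1], nf)))
}

filtfilt_ss <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  n <- length(x)
  nf <- max(length(a), length(b)) - 1L
  pad <- min(n - 1L, max(3L * nf, 100L))
  if (pad < 1L) stop("signal too short to filter", call. = FALSE)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- filter_steady(b, a, xp)
  y <- rev(filter_steady(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

butter_lowpass <- function(cutoff_hz, fs, order = 3) {
  if (cutoff_hz >= fs / 2) {
    stop(sprintf("low-pass cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, fs / 2), call. = FALSE)
  }
  signal::butter(order, cutoff_hz * 2 / fs, type = "low")
}

butter_bandpass <- function(lo_hz, hi_hz, fs, order = 3) {
  if (!(lo_hz > 0 && lo_hz < hi_hz)) {
    stop("band edges must satisfy 0 < lo < hi", call. = FALSE)
  }
  if (hi_hz >= fs / 2) {
    stop(sprintf("band-pass upper edge (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 hi_hz, fs / 2), call. = FALSE)
  }
  signal::butter(order, c(lo_hz, hi_hz) * 2 / fs, type = "pass")
}
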