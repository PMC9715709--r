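#' Decimate a recording by keeping every k-th sample
#'
#' Plain keep-every-k-th decimation with no anti-alias filter, reproducing
#' the behaviour of classic `downsample`-style routines. The EGG analysis
#' band lies far below the decimated Nyquist frequency and the chain applies
#' a 1 Hz low-pass immediately afterwards, so aliasing of slow-wave content
#' is negligible; this is a deliberate fidelity-over-hygiene choice.
#'
#' @param rec An [egg_recording()].
#' @param factor Positive integer decimation factor; `rec`'s sampling rate
#'   must be divisible by it (e.g. 2000 Hz with factor 4 gives 500 Hz).
#' @return The decimated `egg_recording` (stage `downsampled`).
#' @export
egg_downsample <- function(rec, factor = 4L) {
  fs <- egg_fs(rec)
  if (length(factor) != 1 || is.na(factor) || factor < 1 || factor != round(factor)) {
    stop("`factor` must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (abs(fs / factor - round(fs / factor)) > 1e-9) {
    stop(sprintf("sampling rate %g Hz is not divisible by factor %d", fs, factor),
         call. = FALSE)
  }
  keep <- seq.int(1L, nrow(rec), by = factor)
  new_recording_like(rec, rec$voltage_uV[keep], fs = fs / factor,
                     stage = "downsampled")
}

#' Remove a slow polynomial trend
#'
#' Fits a least-squares polynomial of the given order to the whole recording
#' and subtracts it. The time axis is rescaled to `[-1, 1]` before fitting so
#' the fit stays well conditioned on multi-hour series; the residuals are
#' identical to a fit against raw time.
#'
#' @param rec An [egg_recording()].
#' @param order Polynomial order (default 3; 0 removes the mean).
#' @return The detrended `egg_recording` (stage `detrended`).
#' @export
egg_detrend <- function(rec, order = 3L) {
  n <- nrow(rec)
  if (order < 0 || order != round(order)) {
    stop("`order` must be a non-negative integer", call. = FALSE)
  }
  if (n <= order + 1) {
    stop(sprintf("recording too short (%d samples) for order-%d detrending", n, order),
         call. = FALSE)
  }
  t_range <- range(rec$time_s)
  if (diff(t_range) <= 0) stop("degenerate (constant) time axis", call. = FALSE)
  tn <- 2 * (rec$time_s - t_range[1]) / diff(t_range) - 1
  X <- stats::poly(tn, degree = max(order, 1), raw = FALSE)
  if (order == 0) X <- X[, 0, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, X), rec$voltage_uV)
  new_recording_like(rec, unname(fit$residuals), stage = "detrended")
}

#' Zero-phase low-pass filter
#'
#' Order-3 Butterworth low-pass applied forward and backward (effective order
#' 6, zero phase), so in-band components are not delayed or phase shifted.
#'
#' @param rec An [egg_recording()].
#' @param cutoff_hz Cutoff frequency in Hz (default 1); must be below Nyquist.
#' @param order Butterworth order for each pass (default 3).
#' @return The filtered `egg_recording` (stage `filtered`).
#' @export
egg_lowpass <- function(rec, cutoff_hz = 1, order = 3L) {
  filt <- butter_lowpass(cutoff_hz, egg_fs(rec), order = order)
  new_recording_like(rec, filtfilt_ss(filt, rec$voltage_uV), stage = "filtered")
}

#' Standard EGG preprocessing chain
#'
#' Applies, in order: keep-every-k-th decimation (default 2000 to 500 Hz),
#' order-3 polynomial detrending over the whole recording, and a zero-phase
#' 1 Hz Butterworth low-pass.
#'
#' @param rec A raw [egg_recording()].
#' @param downsample_factor Decimation factor (default 4).
#' @param detrend_order Polynomial order for detrending (default 3).
#' @param lowpass_hz Low-pass cutoff in Hz (default 1).
#' @return The conditioned `egg_recording` (stage `filtered`).
#' @examples
#' raw <- egg_recording(rnorm(4 * 60 * 20), fs = 20)
#' pre <- preprocess_egg(raw, downsample_factor = 4)
#' egg_fs(pre)
#' @export
preprocess_egg <- function(rec, downsample_factor = 4L, detrend_order = 3L,
                           lowpass_hz = 1) {
  rec |>
    egg_downsample(downsample_factor) |>
    egg_detrend(detrend_order) |>
    egg_lowpass(lowpass_hz)
}
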