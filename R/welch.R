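#' Welch power spectral density of an EGG segment
#'
#' Averaged modified periodogram with a Hamming taper: the segment is cut
#' into windows of `window_s` seconds advancing by `window_s - overlap_s`
#' (default 4 min windows with 2 min overlap, i.e. 50%), each window is
#' tapered and its periodogram computed, and the periodograms are averaged.
#' One-sided density scaling is used, so for a unit-amplitude tone the
#' density integrates to the tone power (0.5), and for white noise of
#' variance `sigma^2` the density is flat at `sigma^2 / (fs / 2)`.
#'
#' Segments shorter than one window are analysed with a single window equal
#' to the whole segment (with a warning about the degraded resolution);
#' segments shorter than `min_s` seconds are rejected, because below that the
#' bradygastria band no longer contains a full frequency bin.
#'
#' @param segment An [egg_recording()] (one sub-feeding window).
#' @param window_s Welch window length in seconds (default 240).
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (default 120).
#' @param taper Taper applied to each window: `"hamming"` (default),
#'   `"hann"` or `"rect"`.
#' @param detrend_windows Subtract each window's mean before tapering
#'   (default `FALSE`: the chain detrends globally upstream).
#' @param min_s Minimum admissible segment length in seconds (default 125).
#' @return A tibble of class `egg_psd` with columns `freq_hz`, `freq_cpm`,
#'   `psd` (microvolt^2 / Hz), and attributes `resolution_hz`, `window_s`,
#'   `n_windows`, `fs`, `window_label`.
#' @examples
#' rec <- egg_recording(sin(2 * pi * 0.05 * seq(0, 1800, by = 0.25)), fs = 4)
#' psd <- welch_psd(rec)
#' attr(psd, "resolution_hz")
#' @export
welch_psd <- function(segment, window_s = 240, overlap_s = 120,
                      taper = c("hamming", "hann", "rect"),
                      detrend_windows = FALSE, min_s = 125) {
  taper <- match.arg(taper)
  fs <- egg_fs(segment)
  x <- segment$voltage_uV
  n <- length(x)
  if (n == 0) stop("empty segment", call. = FALSE)
  if (n / fs < min_s) {
    stop(sprintf("segment too short (%.1f s): at least %g s are required for a full bradygastria bin",
                 n / fs, min_s), call. = FALSE)
  }
  L <- round(window_s * fs)
  if (n < L) {
    warning(sprintf("segment (%.0f s) shorter than the %g s Welch window; using a single full-length window (resolution degraded to %.3g Hz)",
                    n / fs, window_s, fs / n), call. = FALSE)
    L <- n
  }
  step <- L - round(overlap_s * fs)
  if (step < 1) stop("`overlap_s` must be smaller than `window_s`", call. = FALSE)
  starts <- seq.int(1L, n - L + 1L, by = step)

  w <- switch(taper,
              hamming = 0.54 - 0.46 * cos(2 * pi * seq_len(L) / (L + 1)),
              hann = 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)),
              rect = rep(1, L))
  scale <- 1 / (fs * sum(w^2))
  n_half <- L %/% 2 + 1L

  acc <- numeric(n_half)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    if (detrend_windows) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(n_half)]
    acc <- acc + Re(X * Conj(X))
  }
  pxx <- acc * scale / length(starts)
  # one-sided: double every bin except DC (and Nyquist when L is even)
  dbl <- rep(2, n_half)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[n_half] <- 1
  pxx <- pxx * dbl

  freqs <- (seq_len(n_half) - 1L) * fs / L
  out <- tibble::tibble(freq_hz = freqs, freq_cpm = freqs * 60, psd = pxx)
  attr(out, "resolution_hz") <- fs / L
  attr(out, "window_s") <- L / fs
  attr(out, "n_windows") <- length(starts)
  attr(out, "fs") <- fs
  attr(out, "window_label") <- attr(segment, "window_label") %||% NA_character_
  class(out) <- c("egg_psd", class(out))
  out
}

#' Spectral mean of the PSD over each gastric rhythm band
#'
#' The band spectral mean mPSD is the arithmetic mean of the power spectral
#' density over the frequency bins whose centre falls in the half-open band
#' `[lo_hz, hi_hz)`. Units are those of the density (microvolt^2 / Hz).
#'
#' @param psd An `egg_psd` from [welch_psd()], or any data frame with
#'   `freq_hz` and `psd` columns.
#' @param bands Band definition tibble (default [gastric_bands()]).
#' @return A tibble with columns `band` and `mpsd`.
#' @examples
#' rec <- egg_recording(sin(2 * pi * 0.05 * seq(0, 1800, by = 0.25)), fs = 4)
#' band_mean_psd(welch_psd(rec))
#' @export
band_mean_psd <- function(psd, bands = gastric_bands()) {
  purrr::map_dfr(seq_len(nrow(bands)), function(i) {
    sel <- psd$freq_hz >= bands$lo_hz[i] & psd$freq_hz < bands$hi_hz[i]
    if (!any(sel)) {
      stop(sprintf("no PSD bins inside the %s band [%g, %g) Hz: use a Welch window of at least %.0f s",
                   bands$band[i], bands$lo_hz[i], bands$hi_hz[i],
                   ceiling(1 / (bands$hi_hz[i] - bands$lo_hz[i]))), call. = FALSE)
    }
    tibble::tibble(band = bands$band[i], mpsd = mean(psd$psd[sel]))
  })
}

#' Band-mean PSD for every sub-feeding window of a recording
#'
#' Convenience wrapper: extracts each window, runs [welch_psd()] and
#' [band_mean_psd()], and returns one tidy row per window and band.
#'
#' @param rec A preprocessed [egg_recording()].
#' @param windows Window tibble from [segment_feeds()].
#' @param ... Passed to [welch_psd()].
#' @return Tibble with columns `window_label`, `phase`, `band`, `mpsd`.
#' @export
mpsd_by_window <- function(rec, windows, ...) {
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    seg <- extract_window(rec, windows[i, ])
    band_mean_psd(welch_psd(seg, ...)) |>
      dplyr::mutate(window_label = windows$window_label[i],
                    phase = windows$phase[i], .before = 1)
  })
}

#' Average band features over the two feeding epochs
#'
#' Averages a per-window feature between the two windows of each phase
#' (Pre-feed 1 with Pre-feed 2, and so on), giving one value per phase and
#' band.
#'
#' @param per_window Tidy tibble with columns `window_label`, `band`, and the
#'   value column.
#' @param value Name of the value column (default `"mpsd"`).
#' @param allow_single If `TRUE`, a phase represented by a single window
#'   passes that window's value through (flagged by `n_windows = 1`);
#'   otherwise both windows are required.
#' @return Tibble with columns `phase`, `band`, the value column (phase
#'   mean), and `n_windows`.
#' @export
phase_average <- function(per_window, value = "mpsd", allow_single = FALSE) {
  stopifnot(value %in% names(per_window))
  out <- per_window |>
    dplyr::mutate(phase = window_phase(.data$window_label)) |>
    dplyr::group_by(.data$phase, .data$band) |>
    dplyr::summarise("{value}" := mean(.data[[value]]),
                     n_windows = dplyr::n(), .groups = "drop")
  if (!allow_single && any(out$n_windows < 2)) {
    stop("a phase is represented by a single window; set allow_single = TRUE to accept it",
         call. = FALSE)
  }
  if (any(out$n_windows == 0)) stop("a phase has no windows", call. = FALSE)
  out
}
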