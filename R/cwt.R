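#' Zero-phase gastric band-pass filter
#'
#' Order-3 Butterworth band-pass over the gastric range (default 0.5--15
#' cpm), applied forward-backward so no phase shift is introduced. Because
#' the band edges are tiny fractions of a clinical sampling rate (0.0083 Hz
#' against 500 Hz), the recording is first decimated to `analysis_fs` --
#' its content is already confined below 1 Hz by the preprocessing low-pass
#' -- and the filter is designed at that rate, where it is numerically well
#' conditioned.
#'
#' @param rec A preprocessed [egg_recording()].
#' @param lo_cpm,hi_cpm Band edges in cycles per minute (default 0.5 and 15).
#' @param analysis_fs Working sampling rate in Hz (default 4); the
#'   recording's rate must be an integer multiple of it.
#' @param order Butterworth order per pass (default 3).
#' @return The band-passed `egg_recording` at `analysis_fs`.
#' @export
bandpass_gastric <- function(rec, lo_cpm = 0.5, hi_cpm = 15, analysis_fs = 4,
                             order = 3L) {
  if (!(lo_cpm > 0 && lo_cpm < hi_cpm)) stop("invalid band", call. = FALSE)
  fs <- egg_fs(rec)
  if (fs > analysis_fs) {
    factor <- fs / analysis_fs
    if (abs(factor - round(factor)) > 1e-9) {
      stop(sprintf("sampling rate %g Hz is not an integer multiple of analysis_fs = %g Hz",
                   fs, analysis_fs), call. = FALSE)
    }
    rec <- egg_downsample(rec, round(factor))
  }
  filt <- butter_bandpass(lo_cpm / 60, hi_cpm / 60, egg_fs(rec), order = order)
  new_recording_like(rec, filtfilt_ss(filt, rec$voltage_uV), stage = "filtered")
}

# Wavelet family geometry, all expressed against the dimensionless angular
# frequency w = scale * omega:
#   * peak: w at which the frequency response is maximal,
#   * support: [wlo, whi] outside which the response is below 2e-17 and is
#     treated as zero (the transform touches only those FFT bins),
#   * efold1: e-folding time (s) of the time-domain envelope for a component
#     at 1 Hz; it scales as 1/f and defines the cone of influence.
# Morlet has closed forms; Morse quantities are measured once and cached.
wavelet_geometry <- local({
  cache <- list()
  function(wavelet, omega0 = 6, gamma = 3, beta = 20) {
    key <- paste(wavelet, omega0, gamma, beta)
    if (!is.null(cache[[key]])) return(cache[[key]])
    thr <- log(1e-17)
    geom <- if (wavelet == "morlet") {
      hw <- sqrt(-2 * thr)
      list(peak = omega0, wlo = max(omega0 - hw, 1e-12), whi = omega0 + hw,
           efold1 = sqrt(2) * omega0 / (2 * pi))
    } else {
      omega_p <- (beta / gamma)^(1 / gamma)
      g <- function(w) beta * log(w / omega_p) - (w^gamma - omega_p^gamma) - thr
      wlo <- stats::uniroot(g, c(omega_p * 1e-6, omega_p), tol = 1e-10)$root
      whi <- stats::uniroot(g, c(omega_p, omega_p * 50), tol = 1e-10)$root
      # e-folding time from the synthesized mother wavelet at 1 Hz peak
      nfft <- 2^14; fs <- 64
      om <- 2 * pi * (seq_len(nfft) - 1) * fs / nfft
      keep <- seq_len(nfft %/% 2)
      a <- omega_p / (2 * pi)
      H <- numeric(nfft)
      w <- a * om[keep]
      pos <- w > 0
      H[keep][pos] <- exp(beta * log(w[pos] / omega_p) - (w[pos]^gamma - omega_p^gamma))
      psi <- stats::fft(H, inverse = TRUE) / nfft
      env <- Mod(psi)
      pk <- which.max(env)
      below <- which(env[pk:length(env)] < env[pk] / exp(1))
      list(peak = omega_p, wlo = wlo, whi = whi, efold1 = (below[1] - 1) / fs)
    }
    cache[[key]] <<- geom
    geom
  }
})

wavelet_response <- function(w, wavelet) {
  if (wavelet == "morlet") {
    2 * exp(-((w - 6)^2) / 2)
  } else {
    gamma <- 3; beta <- 20
    omega_p <- (beta / gamma)^(1 / gamma)
    2 * exp(beta * log(w / omega_p) - (w^gamma - omega_p^gamma))
  }
}

#' Continuous wavelet transform spectrogram
#'
#' Analytic continuous wavelet transform power on a logarithmic frequency
#' grid covering at least the gastric range, with a cone-of-influence (COI)
#' mask marking the edge region where coefficients are contaminated by
#' boundary effects. Two analytic families are provided: Morlet (centre
#' frequency `omega0 = 6`, the default) and generalized Morse
#' (`gamma = 3`, `beta = 20`, time-bandwidth product 60). Amplitude (L1)
#' normalisation is used, so a sinusoid of amplitude A attains coefficient
#' magnitude ~A at its own frequency regardless of scale, which makes power
#' directly comparable across bands.
#'
#' The recording is decimated to `analysis_fs` first (its content lies below
#' 0.25 Hz after the gastric band-pass), and the transform is computed by
#' zero-padded FFT, each scale touching only the FFT bins where the
#' wavelet's frequency response is non-negligible.
#'
#' @param rec A band-passed [egg_recording()] (see [bandpass_gastric()]).
#' @param wavelet `"morlet"` (default) or `"morse"`.
#' @param voices Voices per octave of the frequency grid (default 12).
#' @param fmin_cpm,fmax_cpm Grid limits in cpm (defaults 0.4 and 16, chosen
#'   to bracket the 0.5--15 cpm analysis range).
#' @param analysis_fs Working sampling rate in Hz (default 4).
#' @return An object of class `egg_cwt`: a list with `time_s` (seconds from
#'   segment start), `freq_cpm` (increasing log-spaced grid),
#'   `power` (frequency x time matrix of squared coefficient magnitude),
#'   `coi` (logical matrix, `TRUE` where a cell lies inside the cone of
#'   influence and must be excluded), `fs`, `wavelet`.
#' @examples
#' rec <- egg_recording(sin(2 * pi * 0.05 * seq(0, 600, by = 0.25)), fs = 4)
#' cw <- cwt_power(rec)
#' range(cw$freq_cpm)
#' @export
cwt_power <- function(rec, wavelet = c("morlet", "morse"), voices = 12,
                      fmin_cpm = 0.4, fmax_cpm = 16, analysis_fs = 4) {
  wavelet <- match.arg(wavelet)
  fs <- egg_fs(rec)
  if (fs > analysis_fs) {
    factor <- fs / analysis_fs
    if (abs(factor - round(factor)) > 1e-9) {
      stop(sprintf("sampling rate %g Hz is not an integer multiple of analysis_fs = %g Hz",
                   fs, analysis_fs), call. = FALSE)
    }
    rec <- egg_downsample(rec, round(factor))
    fs <- egg_fs(rec)
  }
  x <- rec$voltage_uV - mean(rec$voltage_uV)
  n <- length(x)
  if (n / fs < 120) {
    stop("recording shorter than 2 minutes: entirely inside the cone of influence",
         call. = FALSE)
  }

  n_oct <- log2(fmax_cpm / fmin_cpm)
  k <- 0:ceiling(voices * n_oct)
  freq_cpm <- fmin_cpm * 2^(k / voices)
  freq_hz <- freq_cpm / 60
  nf <- length(freq_hz)

  geom <- wavelet_geometry(wavelet)
  max_tau <- geom$efold1 / min(freq_hz)
  nfft <- stats::nextn(n + ceiling(max_tau * fs), c(2, 3))
  X <- stats::fft(c(x, numeric(nfft - n)))
  half <- nfft %/% 2
  dom <- 2 * pi * fs / nfft                 # angular frequency per bin

  scales <- geom$peak / (2 * pi * freq_hz)
  # FFT bins (1-based, DC excluded) inside each scale's spectral support
  j0 <- pmax(2L, floor(geom$wlo / (scales * dom)) + 1L)
  j1 <- pmin(half, ceiling(geom$whi / (scales * dom)) + 1L)
  resp <- lapply(seq_len(nf), function(i) {
    wavelet_response(scales[i] * dom * (j0[i]:j1[i] - 1L), wavelet)
  })
  power <- cwt_power_engine(X, n, as.integer(j0), as.integer(j1), resp)

  time_s <- (seq_len(n) - 1) / fs
  tau <- geom$efold1 / freq_hz              # e-folding time per row, seconds
  coi <- matrix(FALSE, nrow = nf, ncol = n)
  edge <- pmin(ceiling(tau * fs), n)        # samples inside the cone per side
  for (i in seq_len(nf)) {
    k <- edge[i]
    if (k > 0) coi[i, c(seq_len(k), (n - k + 1):n)] <- TRUE
  }

  structure(list(time_s = time_s, freq_cpm = freq_cpm, power = power,
                 coi = coi, fs = fs, wavelet = wavelet),
            class = "egg_cwt")
}

#' @export
print.egg_cwt <- function(x, ...) {
  cat(sprintf("<egg_cwt> %s wavelet | %d freqs (%.2g-%.3g cpm) x %d times (%.1f min) | %.0f%% of cells in COI\n",
              x$wavelet, length(x$freq_cpm), min(x$freq_cpm), max(x$freq_cpm),
              length(x$time_s), max(x$time_s) / 60, 100 * mean(x$coi)))
  invisible(x)
}
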