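#' Per-minute dominant-rhythm partition of a CWT spectrogram
#'
#' For every whole minute of the spectrogram, the wavelet power is averaged
#' over time and over the frequencies of each gastric rhythm band, cells
#' inside the cone of influence being excluded from every mean. Each band
#' mean is divided by the mean power over the whole gastric range
#' (0.5--9 cpm) for the same minute, and the band with the largest ratio is
#' the minute's dominant rhythm. Minutes whose gastric-range cells are all
#' COI-masked are labelled `unclassified`. Ties (a probability-zero event on
#' real signals) resolve to the lower-frequency band. A trailing partial
#' minute is dropped.
#'
#' @param cw An `egg_cwt` from [cwt_power()].
#' @param bands Band definition tibble (default [gastric_bands()]).
#' @return A tibble with columns `minute` (0-based index), `ratio_brady`,
#'   `ratio_normo`, `ratio_tachy`, `dominant` (factor with the band levels,
#'   `NA` when unclassified), `coi_fraction` (fraction of the minute's
#'   gastric-range cells that were masked).
#' @examples
#' rec <- egg_recording(sin(2 * pi * 0.05 * seq(0, 600, by = 0.25)), fs = 4)
#' minute_band_ratios(cwt_power(rec))
#' @export
minute_band_ratios <- function(cw, bands = gastric_bands()) {
  stopifnot(inherits(cw, "egg_cwt"))
  spm <- round(60 * cw$fs)                   # samples per minute
  n_min <- length(cw$time_s) %/% spm
  if (n_min < 1) stop("spectrogram shorter than one whole minute", call. = FALSE)
  n_use <- n_min * spm

  # per-minute sums of valid (non-COI) power and of valid-cell counts, per
  # band; the three bands partition the 0.5-9 cpm total range, so the total
  # mean is assembled from the band sums
  rows_band <- lapply(seq_len(nrow(bands)), function(i) {
    which(cw$freq_cpm >= bands$lo_cpm[i] & cw$freq_cpm < bands$hi_cpm[i])
  })
  by_minute <- function(v) colSums(matrix(v, nrow = spm, ncol = n_min))
  sums <- counts <- matrix(0, nrow = n_min, ncol = nrow(bands))
  for (i in seq_len(nrow(bands))) {
    r <- rows_band[[i]]
    valid <- !cw$coi[r, seq_len(n_use), drop = FALSE]
    sums[, i] <- by_minute(colSums(cw$power[r, seq_len(n_use), drop = FALSE] * valid))
    counts[, i] <- by_minute(colSums(valid))
  }
  tot_num <- rowSums(sums)
  tot_den <- rowSums(counts)
  total <- ifelse(tot_den > 0, tot_num / tot_den, NA_real_)
  band_means <- ifelse(counts > 0, sums / counts, NA_real_)
  ratios <- band_means / total

  coi_fraction <- 1 - tot_den / (length(unlist(rows_band)) * spm)

  dominant <- apply(ratios, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(replace(r, is.na(r), -Inf))
  })
  tibble::tibble(
    minute = seq_len(n_min) - 1L,
    ratio_brady = ratios[, 1],
    ratio_normo = ratios[, 2],
    ratio_tachy = ratios[, 3],
    dominant = factor(band_levels()[dominant], levels = band_levels()),
    coi_fraction = coi_fraction
  )
}

#' Percent time spent in each gastric rhythm
#'
#' Counts the dominant-band minutes `T_GR` of a partition map and converts
#' them to percentages. With `denominator_mode = "total"` (the default) the
#' denominator is every whole minute of the window, so unclassified minutes
#' dilute all three percentages; with `"classified"` only classified minutes
#' count and the three percentages sum to exactly 100.
#'
#' @param partition A partition tibble from [minute_band_ratios()].
#' @param window_label Optional label attached to the result.
#' @param denominator_mode `"total"` (default) or `"classified"`.
#' @return A one-row tibble with `window_label`, `t_brady`, `t_normo`,
#'   `t_tachy` (dominant-minute counts), `total_minutes`, `n_classified`,
#'   `pct_brady`, `pct_normo`, `pct_tachy`.
#' @examples
#' part <- tibble::tibble(dominant = factor(rep(c("normo", "brady"), c(18, 12)),
#'                                          levels = c("brady", "normo", "tachy")))
#' percent_time(part)
#' @export
percent_time <- function(partition, window_label = NA_character_,
                         denominator_mode = c("total", "classified")) {
  denominator_mode <- match.arg(denominator_mode)
  total <- nrow(partition)
  if (total == 0) stop("zero-minute window", call. = FALSE)
  counts <- table(factor(partition$dominant, levels = band_levels()))
  n_classified <- sum(counts)
  denom <- if (denominator_mode == "total") total else n_classified
  if (denom == 0) stop("no classified minutes in window", call. = FALSE)
  pct <- 100 * as.numeric(counts) / denom
  tibble::tibble(
    window_label = window_label,
    t_brady = as.integer(counts[1]), t_normo = as.integer(counts[2]),
    t_tachy = as.integer(counts[3]),
    total_minutes = total, n_classified = n_classified,
    pct_brady = pct[1], pct_normo = pct[2], pct_tachy = pct[3]
  )
}

#' Percent time in each rhythm for every sub-feeding window
#'
#' Runs the time-frequency chain per feeding epoch: the contiguous
#' pre/during/post span of each feeding is extracted, band-passed over the
#' gastric range, transformed with the CWT (cone of influence falling at the
#' epoch edges, as in a feeding-epoch spectrogram), and partitioned into
#' per-minute dominant rhythms; minutes are then counted per sub-feeding
#' window.
#'
#' @param rec A preprocessed [egg_recording()].
#' @param windows Window tibble from [segment_feeds()].
#' @param wavelet,voices,analysis_fs Passed to [cwt_power()].
#' @param denominator_mode Passed to [percent_time()].
#' @param lo_cpm,hi_cpm Band-pass edges in cpm (defaults 0.5 and 15).
#' @return Tibble with one row per window: the [percent_time()] columns plus
#'   `phase`.
#' @export
percent_time_by_window <- function(rec, windows, wavelet = "morlet",
                                   voices = 12, analysis_fs = 4,
                                   denominator_mode = "total",
                                   lo_cpm = 0.5, hi_cpm = 15) {
  epoch <- sub("^.*([12])$", "\\1", as.character(windows$window_label))
  out <- purrr::map_dfr(unique(epoch), function(ep) {
    w_ep <- windows[epoch == ep, , drop = FALSE]
    span <- tibble::tibble(start_min = min(w_ep$start_min),
                           end_min = max(w_ep$end_min))
    seg <- extract_window(rec, span) |>
      bandpass_gastric(lo_cpm, hi_cpm, analysis_fs = analysis_fs)
    part <- minute_band_ratios(cwt_power(seg, wavelet = wavelet, voices = voices,
                                         analysis_fs = analysis_fs))
    purrr::map_dfr(seq_len(nrow(w_ep)), function(i) {
      m0 <- ceiling(w_ep$start_min[i] - span$start_min)
      m1 <- floor(w_ep$end_min[i] - span$start_min)
      percent_time(part[part$minute >= m0 & part$minute < m1, , drop = FALSE],
                   window_label = as.character(w_ep$window_label[i]),
                   denominator_mode = denominator_mode)
    })
  })
  dplyr::mutate(out, phase = window_phase(.data$window_label),
                .after = "window_label")
}

#' Average percent-time features over the two feeding epochs
#'
#' Unweighted mean of the two windows of each phase, per band (Pre-feed 1
#' with Pre-feed 2, and so on).
#'
#' @param pct Tibble from [percent_time_by_window()].
#' @param allow_single Accept phases represented by a single window
#'   (default `FALSE`).
#' @return Tibble with columns `phase`, `band`, `pct`, `n_windows`.
#' @export
phase_average_pct <- function(pct, allow_single = FALSE) {
  long <- pct |>
    tidyr::pivot_longer(dplyr::all_of(c("pct_brady", "pct_normo", "pct_tachy")),
                        names_to = "band", names_prefix = "pct_",
                        values_to = "pct") |>
    dplyr::mutate(band = factor(.data$band, levels = band_levels()))
  phase_average(long, value = "pct", allow_single = allow_single)
}
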