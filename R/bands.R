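#' Gastric rhythm frequency bands
#'
#' The three canonical gastric rhythm (GR) bands used throughout the package:
#' bradygastria, normogastria and tachygastria. Bands are half-open intervals
#' `[lo, hi)` in cycles per minute (cpm); the Hz columns are the exact
#' conversions `cpm / 60`. Together the bands partition the gastric spectrum
#' 0.5--9 cpm with no gap or overlap.
#'
#' @return A tibble with columns `band` (factor with levels `brady`, `normo`,
#'   `tachy`, ordered from low to high frequency), `lo_cpm`, `hi_cpm`,
#'   `lo_hz`, `hi_hz`.
#' @examples
#' gastric_bands()
#' @export
gastric_bands <- function() {
  tibble::tibble(
    band   = factor(c("brady", "normo", "tachy"),
                    levels = c("brady", "normo", "tachy")),
    lo_cpm = c(0.5, 2, 4),
    hi_cpm = c(2, 4, 9),
    lo_hz  = c(0.5, 2, 4) / 60,
    hi_hz  = c(2, 4, 9) / 60
  )
}

#' Convert cycles per minute to Hz
#'
#' @param cpm Frequency in cycles per minute.
#' @return Frequency in Hz (`cpm / 60`).
#' @export
cpm_to_hz <- function(cpm) cpm / 60

#' Convert Hz to cycles per minute
#'
#' @param hz Frequency in Hz.
#' @return Frequency in cycles per minute (`hz * 60`).
#' @export
hz_to_cpm <- function(hz) hz * 60

#' Classify a frequency into a gastric rhythm band
#'
#' Assigns each frequency (in cpm) to the half-open band that contains it, or
#' `NA` when the frequency falls outside the gastric range `[0.5, 9)` cpm.
#'
#' @param cpm Numeric vector of frequencies in cycles per minute.
#' @return Factor with levels `brady`, `normo`, `tachy` (and `NA` outside the
#'   gastric range).
#' @examples
#' band_of_cpm(c(1, 3, 6, 12))
#' @export
band_of_cpm <- function(cpm) {
  bands <- gastric_bands()
  idx <- rep(NA_integer_, length(cpm))
  for (i in seq_len(nrow(bands))) {
    idx[cpm >= bands$lo_cpm[i] & cpm < bands$hi_cpm[i]] <- i
  }
  factor(levels(bands$band)[idx], levels = levels(bands$band))
}

band_levels <- function() c("brady", "normo", "tachy")

phase_levels <- function() c("pre", "during", "post")

window_levels <- function() c("pre1", "during1", "post1", "pre2", "during2", "post2")

#' Map a sub-feeding window label to its feeding phase
#'
#' `pre1`/`pre2` map to `pre`, `during1`/`during2` to `during`,
#' `post1`/`post2` to `post`.
#'
#' @param label Character vector of window labels.
#' @return Factor with levels `pre`, `during`, `post`.
#' @export
window_phase <- function(label) {
  phase <- sub("[12]$", "", as.character(label))
  bad <- !phase %in% phase_levels() & !is.na(phase)
  if (any(bad)) {
    stop("unrecognised window label(s): ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  factor(phase, levels = phase_levels())
}
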