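#' Construct an EGG recording
#'
#' An `egg_recording` is a tibble with columns `time_s` (seconds from
#' recording start) and `voltage_uV` (microvolts), carrying the sampling rate
#' and bookkeeping metadata as attributes. All processing functions in the
#' package take and return this shape, so recordings flow through pipes.
#'
#' @param voltage_uV Numeric vector of voltage samples in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0_s Time of the first sample in seconds (default 0).
#' @param subject_id Optional subject identifier.
#' @param stage Processing stage tag, one of `"raw"`, `"downsampled"`,
#'   `"detrended"`, `"filtered"`.
#' @return A tibble of class `egg_recording` with columns `time_s`,
#'   `voltage_uV`.
#' @examples
#' rec <- egg_recording(sin(2 * pi * 0.05 * seq(0, 60, by = 0.25)), fs = 4)
#' rec
#' @export
egg_recording <- function(voltage_uV, fs, t0_s = 0, subject_id = NA_character_,
                          stage = "raw") {
  stopifnot(is.numeric(voltage_uV), length(voltage_uV) > 0)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(voltage_uV))) {
    stop("voltage samples must all be finite", call. = FALSE)
  }
  stage <- match.arg(stage, c("raw", "downsampled", "detrended", "filtered"))
  out <- tibble::tibble(
    time_s = t0_s + (seq_along(voltage_uV) - 1) / fs,
    voltage_uV = as.numeric(voltage_uV)
  )
  attr(out, "fs") <- fs
  attr(out, "subject_id") <- subject_id
  attr(out, "stage") <- stage
  class(out) <- c("egg_recording", class(out))
  out
}

new_recording_like <- function(rec, voltage_uV, fs = egg_fs(rec), stage = egg_stage(rec),
                               t0_s = rec$time_s[1]) {
  egg_recording(voltage_uV, fs = fs, t0_s = t0_s,
                subject_id = attr(rec, "subject_id"), stage = stage)
}

#' @rdname egg_recording
#' @param rec An `egg_recording`.
#' @export
egg_fs <- function(rec) {
  fs <- attr(rec, "fs")
  if (is.null(fs)) stop("not an egg_recording: missing `fs` attribute", call. = FALSE)
  fs
}

#' @rdname egg_recording
#' @export
egg_stage <- function(rec) attr(rec, "stage") %||% "raw"

#' @rdname egg_recording
#' @export
egg_duration_min <- function(rec) nrow(rec) / egg_fs(rec) / 60

egg_signal <- function(rec) rec$voltage_uV

#' @export
print.egg_recording <- function(x, ...) {
  cat(sprintf("<egg_recording> %s | fs = %g Hz | %d samples (%.2f min) | stage: %s\n",
              attr(x, "subject_id") %||% "?", egg_fs(x), nrow(x),
              egg_duration_min(x), egg_stage(x)))
  NextMethod()
}

`%||%` <- function(x, y) if (is.null(x)) y else x
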