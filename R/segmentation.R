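#' Derive the six sub-feeding analysis windows
#'
#' Builds the Pre-/During-/Post-feed windows around two consecutive enteral
#' feeds. During-feed windows equal the feed events themselves. Pre-feed 1 is
#' the up-to-30 minutes immediately before feed 1 (truncated at the recording
#' start); Post-feed 2 is the up-to-30 minutes after feed 2 (truncated at the
#' recording end). The interval between the feeds is split at its midpoint:
#' Post-feed 1 lies in the first half adjacent to the end of feed 1, and
#' Pre-feed 2 in the second half adjacent to the start of feed 2. With
#' `halves_mode = "capped"` (default) each of those is at most 30 minutes;
#' with `"full"` each takes its whole half, however long. Windows shorter
#' than the nominal 30 minutes are kept and flagged `truncated`.
#'
#' @param feeds A data frame (or tibble) of feed events with columns
#'   `start_min` and `end_min`, minutes from recording start. Exactly two
#'   feeds are expected; a single feed is accepted only with
#'   `allow_single_feed = TRUE`, in which case just the Feeding-1 windows
#'   (`pre1`, `during1`, `post1`) are returned and `post1` is the up-to-30
#'   minutes after the feed.
#' @param duration_min Recording duration in minutes.
#' @param nominal_min Nominal pre/post window length in minutes (default 30).
#' @param halves_mode `"capped"` (default) or `"full"`; see Details.
#' @param allow_single_feed Accept a one-feed schedule (default `FALSE`).
#' @return A tibble with columns `window_label` (factor `pre1` ... `post2`),
#'   `phase`, `start_min`, `end_min`, `duration_min`, `truncated`.
#' @examples
#' feeds <- tibble::tibble(start_min = c(30, 156), end_min = c(60, 186))
#' segment_feeds(feeds, duration_min = 216)
#' @export
segment_feeds <- function(feeds, duration_min, nominal_min = 30,
                          halves_mode = c("capped", "full"),
                          allow_single_feed = FALSE) {
  halves_mode <- match.arg(halves_mode)
  stopifnot(is.data.frame(feeds), all(c("start_min", "end_min") %in% names(feeds)))
  feeds <- feeds[order(feeds$start_min), , drop = FALSE]
  if (any(feeds$end_min <= feeds$start_min)) {
    stop("each feed must have end_min > start_min", call. = FALSE)
  }
  if (any(feeds$start_min < 0) || any(feeds$end_min > duration_min)) {
    stop("feeds must lie within the recording", call. = FALSE)
  }
  n <- nrow(feeds)
  if (n == 1 && allow_single_feed) {
    w <- tibble::tibble(
      window_label = c("pre1", "during1", "post1"),
      start_min = c(max(0, feeds$start_min[1] - nominal_min), feeds$start_min[1],
                    feeds$end_min[1]),
      end_min = c(feeds$start_min[1], feeds$end_min[1],
                  min(duration_min, feeds$end_min[1] + nominal_min))
    )
  } else if (n == 2) {
    if (nrow(feeds) > 1 && any(feeds$start_min[-1] < feeds$end_min[-n])) {
      stop("feed windows overlap", call. = FALSE)
    }
    gap <- feeds$start_min[2] - feeds$end_min[1]
    if (gap <= 0) stop("inter-feed gap must be positive", call. = FALSE)
    mid <- feeds$end_min[1] + gap / 2
    half <- if (halves_mode == "capped") min(gap / 2, nominal_min) else gap / 2
    w <- tibble::tibble(
      window_label = window_levels(),
      start_min = c(max(0, feeds$start_min[1] - nominal_min), feeds$start_min[1],
                    feeds$end_min[1], feeds$start_min[2] - half,
                    feeds$start_min[2], feeds$end_min[2]),
      end_min = c(feeds$start_min[1], feeds$end_min[1],
                  feeds$end_min[1] + half, feeds$start_min[2],
                  feeds$end_min[2],
                  min(duration_min, feeds$end_min[2] + nominal_min))
    )
  } else {
    stop(sprintf(paste0("expected exactly two feeds (got %d); multi-feed ",
                        "recordings are out of scope and a single feed needs ",
                        "allow_single_feed = TRUE"), n), call. = FALSE)
  }
  w$window_label <- factor(w$window_label, levels = window_levels())
  w$phase <- window_phase(w$window_label)
  w$duration_min <- w$end_min - w$start_min
  w$truncated <- w$phase != "during" & w$duration_min < nominal_min - 1e-9
  w[, c("window_label", "phase", "start_min", "end_min", "duration_min", "truncated")]
}

#' Extract one sub-feeding window from a recording
#'
#' Slices the half-open interval `[start_min, end_min)` out of a recording,
#' converting minute boundaries to sample indices by flooring.
#'
#' @param rec An [egg_recording()].
#' @param window One row of the tibble returned by [segment_feeds()] (or any
#'   data frame row with `start_min` and `end_min`).
#' @return The sliced `egg_recording`; its `time_s` keeps the original clock.
#' @export
extract_window <- function(rec, window) {
  stopifnot(nrow(window) == 1)
  fs <- egg_fs(rec)
  i0 <- floor(window$start_min * 60 * fs) + 1L
  i1 <- floor(window$end_min * 60 * fs)
  if (i1 < i0) stop("zero-length window", call. = FALSE)
  if (i0 < 1 || i1 > nrow(rec)) stop("window outside the recording", call. = FALSE)
  new_recording_like(rec, rec$voltage_uV[i0:i1], t0_s = rec$time_s[i0])
}
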