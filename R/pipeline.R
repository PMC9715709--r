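#' Analysis options for the EGG pipeline
#'
#' Bundles every tunable of the analysis chain with its standard default:
#' 4x decimation (2000 to 500 Hz), order-3 detrending, 1 Hz zero-phase
#' low-pass, 240 s Welch windows with 120 s overlap and a Hamming taper,
#' 0.5--15 cpm gastric band-pass, Morlet wavelet at 12 voices per octave on
#' a 4 Hz working rate, whole-window percent-time denominator, capped
#' inter-feed halves, and alpha = 0.05.
#'
#' @param downsample_factor,detrend_order,lowpass_hz Preprocessing settings.
#' @param welch_window_s,welch_overlap_s,welch_taper Welch settings.
#' @param bandpass_lo_cpm,bandpass_hi_cpm Gastric band-pass edges.
#' @param wavelet,voices,analysis_fs CWT settings.
#' @param denominator_mode `"total"` or `"classified"` (see [percent_time()]).
#' @param halves_mode `"capped"` or `"full"` (see [segment_feeds()]).
#' @param allow_single_feed Accept one-feed recordings (Feeding-1 epoch
#'   only); phase values then come from single windows.
#' @param alpha Significance level for the statistics.
#' @return A list of class `egg_options`.
#' @export
egg_options <- function(downsample_factor = 4L, detrend_order = 3L,
                        lowpass_hz = 1, welch_window_s = 240,
                        welch_overlap_s = 120, welch_taper = "hamming",
                        bandpass_lo_cpm = 0.5, bandpass_hi_cpm = 15,
                        wavelet = "morlet", voices = 12, analysis_fs = 4,
                        denominator_mode = "total", halves_mode = "capped",
                        allow_single_feed = FALSE, alpha = 0.05) {
  structure(as.list(environment()), class = "egg_options")
}

feeds_from_params <- function(params) {
  m <- do.call(rbind, params$feed_times)
  tibble::tibble(start_min = m[, 1], end_min = m[, 1] + m[, 2])
}

#' Per-subject feature extraction
#'
#' Runs one recording through the whole chain -- preprocessing, sub-feeding
#' segmentation, Welch band-mean PSD, and CWT percent time in rhythm -- and
#' returns the per-phase features in tidy form.
#'
#' @param rec A raw [egg_recording()].
#' @param feeds Feed schedule data frame (`start_min`, `end_min`).
#' @param opts An [egg_options()] list.
#' @param features Which features to compute: any of `"mpsd"`, `"pct_time"`
#'   (default both).
#' @return Tibble with columns `subject_id`, `phase`, `band`, `feature`
#'   (`"mpsd"` in microvolt^2/Hz or `"pct_time"` in percent), `value`,
#'   `n_windows`.
#' @export
subject_features <- function(rec, feeds, opts = egg_options(),
                             features = c("mpsd", "pct_time")) {
  features <- match.arg(features, several.ok = TRUE)
  pre <- preprocess_egg(rec, opts$downsample_factor, opts$detrend_order,
                        opts$lowpass_hz)
  windows <- segment_feeds(feeds, egg_duration_min(pre),
                           halves_mode = opts$halves_mode,
                           allow_single_feed = opts$allow_single_feed)
  allow_single <- nrow(windows) < 6

  out <- list()
  if ("mpsd" %in% features) {
    out$mpsd <- mpsd_by_window(pre, windows, window_s = opts$welch_window_s,
                               overlap_s = opts$welch_overlap_s,
                               taper = opts$welch_taper) |>
      phase_average(value = "mpsd", allow_single = allow_single) |>
      dplyr::mutate(feature = "mpsd") |>
      dplyr::rename(value = "mpsd")
  }
  if ("pct_time" %in% features) {
    out$pct <- percent_time_by_window(pre, windows, wavelet = opts$wavelet,
                                      voices = opts$voices,
                                      analysis_fs = opts$analysis_fs,
                                      denominator_mode = opts$denominator_mode,
                                      lo_cpm = opts$bandpass_lo_cpm,
                                      hi_cpm = opts$bandpass_hi_cpm) |>
      phase_average_pct(allow_single = allow_single) |>
      dplyr::mutate(feature = "pct_time") |>
      dplyr::rename(value = "pct")
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(subject_id = attr(rec, "subject_id"), .before = 1)
}

#' Cohort feature table
#'
#' Applies [subject_features()] to every subject of a simulated cohort,
#' regenerating recordings from their specs when they were not kept, and
#' joins the gestational-age metadata.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param opts An [egg_options()] list.
#' @param features Which features to compute (see [subject_features()]).
#' @return Tidy tibble: `subject_id`, `ga_weeks`, `ga_group`, `phase`,
#'   `band`, `feature`, `value`, `n_windows`.
#' @export
cohort_features <- function(cohort, opts = egg_options(),
                            features = c("mpsd", "pct_time")) {
  feeds <- feeds_from_params(cohort$params)
  feats <- purrr::map_dfr(seq_along(cohort$specs), function(i) {
    rec <- if (!is.null(cohort$recordings)) {
      cohort$recordings[[i]]$recording
    } else {
      simulate_recording(cohort$specs[[i]], cohort$params)$recording
    }
    subject_features(rec, feeds, opts, features = features)
  })
  dplyr::left_join(feats, cohort$subjects[c("subject_id", "ga_weeks", "ga_group")],
                   by = "subject_id") |>
    dplyr::relocate("ga_weeks", "ga_group", .after = "subject_id")
}

#' Run the full cohort analysis
#'
#' End-to-end driver: simulates a cohort, extracts per-subject features,
#' runs the across-phase ANOVA battery and the gestational-age regression
#' battery, and (optionally) writes tidy CSVs plus a Markdown report.
#'
#' @param n_per_group Subjects per gestational-age group (default 25/22/4).
#' @param params A [sim_params()].
#' @param opts An [egg_options()].
#' @param master_seed Master RNG seed.
#' @param out_dir Optional output directory; when given, `subjects.csv`,
#'   `features.csv`, `anova.csv`, `regressions.csv` and `report.md` are
#'   written there.
#' @return A list of class `egg_pipeline` with `subjects`, `features`,
#'   `anova`, `regressions`, `params`, `opts`, `master_seed`.
#' @export
run_pipeline <- function(n_per_group = c(early = 25, mid = 22, term = 4),
                         params = sim_params(), opts = egg_options(),
                         master_seed = 1, out_dir = NULL) {
  cohort <- simulate_cohort(n_per_group, params, master_seed,
                            keep_recordings = FALSE)
  features <- cohort_features(cohort, opts)
  res <- structure(list(
    subjects = cohort$subjects,
    features = features,
    anova = anova_battery(features, alpha = opts$alpha),
    regressions = regression_battery(features, alpha = opts$alpha),
    params = params, opts = opts, master_seed = master_seed
  ), class = "egg_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.egg_pipeline <- function(x, ...) {
  cat(sprintf("<egg_pipeline> %d subjects | %d feature rows | seed %s\n",
              nrow(x$subjects), nrow(x$features), x$master_seed))
  cat("\nRegressions against gestational age:\n")
  print(x$regressions, n = Inf)
  invisible(x)
}

#' Write pipeline outputs
#'
#' Emits the tidy CSVs and a short Markdown report (cohort make-up, the
#' regression table and the ANOVA table, plus every analysis parameter for
#' provenance) into a directory.
#'
#' @param res An `egg_pipeline` result from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tidy(res$subjects, file.path(out_dir, "subjects.csv"))
  write_tidy(res$features, file.path(out_dir, "features.csv"))
  write_tidy(res$anova, file.path(out_dir, "anova.csv"))
  write_tidy(res$regressions, file.path(out_dir, "regressions.csv"))

  opts <- res$opts
  lines <- c(
    "# EGG cohort analysis report",
    "",
    sprintf("Master seed: %s. Subjects: %d (%s).", res$master_seed,
            nrow(res$subjects),
            paste(sprintf("%s=%d", levels(res$subjects$ga_group),
                          table(res$subjects$ga_group)), collapse = ", ")),
    "",
    "## Parameters",
    "",
    sprintf("- Raw rate %g Hz, decimation factor %d, detrend order %d, low-pass %g Hz",
            res$params$fs_raw, opts$downsample_factor, opts$detrend_order,
            opts$lowpass_hz),
    sprintf("- Welch: %g s window, %g s overlap, %s taper",
            opts$welch_window_s, opts$welch_overlap_s, opts$welch_taper),
    sprintf("- CWT: %s wavelet, %d voices/octave, %g Hz working rate, band-pass %g-%g cpm",
            opts$wavelet, opts$voices, opts$analysis_fs,
            opts$bandpass_lo_cpm, opts$bandpass_hi_cpm),
    sprintf("- Percent-time denominator: %s; inter-feed halves: %s; alpha = %g",
            opts$denominator_mode, opts$halves_mode, opts$alpha),
    "",
    "## Regressions against gestational age",
    "",
    df_to_md(res$regressions),
    "",
    "## ANOVA across feeding phases (Tukey contrasts)",
    "",
    df_to_md(res$anova)
  )
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

df_to_md <- function(df, digits = 4) {
  fmt <- function(v) {
    if (is.numeric(v)) signif(v, digits) else as.character(v)
  }
  d <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE)
  header <- paste0("| ", paste(names(d), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  rows <- apply(d, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}
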