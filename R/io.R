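#' Read an EGG recording from CSV
#'
#' The canonical interchange format is a two-column CSV `time_s, voltage_uV`.
#' The sampling rate is inferred from the time column (and checked for
#' uniformity) unless given explicitly.
#'
#' @param path Path to the CSV file.
#' @param fs Optional sampling rate in Hz; inferred from `time_s` if `NULL`.
#' @param subject_id Optional subject identifier.
#' @return An [egg_recording()].
#' @export
read_egg_csv <- function(path, fs = NULL, subject_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), voltage_uV = readr::col_double()
  ))
  if (!all(c("time_s", "voltage_uV") %in% names(d))) {
    stop("CSV must have columns time_s and voltage_uV", call. = FALSE)
  }
  if (nrow(d) < 2) stop("recording must have at least 2 samples", call. = FALSE)
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
  fs_inferred <- 1 / stats::median(dt)
  if (max(abs(dt - 1 / fs_inferred)) > 0.01 / fs_inferred) {
    stop("time axis is not uniformly sampled", call. = FALSE)
  }
  if (!is.null(fs) && abs(fs - fs_inferred) > 0.01 * fs) {
    stop(sprintf("stated fs (%g Hz) disagrees with the time axis (%g Hz)",
                 fs, fs_inferred), call. = FALSE)
  }
  egg_recording(d$voltage_uV, fs = fs %||% fs_inferred, t0_s = d$time_s[1],
                subject_id = subject_id)
}

#' Write an EGG recording to CSV
#'
#' @param rec An [egg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_egg_csv <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(rec)[c("time_s", "voltage_uV")], path)
  invisible(path)
}

#' Read a feed schedule
#'
#' Accepts either a CSV with columns `start_min`, `end_min` or a YAML file
#' with a top-level `feeds` list of `{start_min, end_min}` entries.
#'
#' @param path Path to the schedule file.
#' @return Tibble with columns `start_min`, `end_min`.
#' @export
read_feed_schedule <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (is.null(y$feeds)) stop("YAML schedule must have a `feeds` list", call. = FALSE)
    d <- purrr::map_dfr(y$feeds, ~ tibble::tibble(start_min = .x$start_min,
                                                  end_min = .x$end_min))
  } else {
    d <- readr::read_csv(path, col_types = readr::cols(
      start_min = readr::col_double(), end_min = readr::col_double()
    ))
  }
  if (!all(c("start_min", "end_min") %in% names(d)) || nrow(d) == 0) {
    stop("feed schedule must provide start_min and end_min", call. = FALSE)
  }
  tibble::as_tibble(d[c("start_min", "end_min")])
}

#' Write a tidy result table
#'
#' Deterministic column order, UTF-8, `NA` written as an empty cell, so
#' write-then-read round-trips and repeated runs are byte-identical.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tidy <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' The configuration mirrors [sim_params()] and [egg_options()]: top-level
#' keys `sim`, `options`, `n_per_group`, `master_seed`, any of which may be
#' omitted to use the defaults.
#'
#' @param path Path to a YAML file.
#' @return List with `params` ([sim_params()]), `opts` ([egg_options()]),
#'   `n_per_group`, `master_seed`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$sim %||% list()
  if (!is.null(sim$feed_times)) {
    sim$feed_times <- lapply(sim$feed_times, unlist)
  }
  params <- do.call(sim_params, sim)
  opts <- do.call(egg_options, y$options %||% list())
  list(params = params, opts = opts,
       n_per_group = unlist(y$n_per_group) %||% c(early = 25, mid = 22, term = 4),
       master_seed = y$master_seed %||% 1)
}
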