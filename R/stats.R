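#' One-way ANOVA across feeding phases with Tukey post-hoc contrasts
#'
#' Compares a feature (band-mean PSD or percent time) across the pre-,
#' during- and post-feed phases within one gestational-age group and band,
#' using `stats::aov()` followed by `stats::TukeyHSD()` for the pairwise
#' phase contrasts.
#'
#' @param data A data frame with a `phase` column and the feature in
#'   `value`; typically a filtered slice of a cohort feature table from
#'   [cohort_features()].
#' @param value Name of the feature column (default `"value"`).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `egg_anova`; use [generics::tidy()] for the
#'   Tukey pairs and [generics::glance()] for the F test.
#' @examples
#' d <- data.frame(phase = rep(c("pre", "during", "post"), each = 5),
#'                 value = rnorm(15))
#' glance(anova_phases(d))
#' @export
anova_phases <- function(data, value = "value", alpha = 0.05) {
  stopifnot(value %in% names(data), "phase" %in% names(data))
  d <- data.frame(phase = factor(data$phase), value = data[[value]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  tab <- table(d$phase)
  tab <- tab[tab > 0]
  if (length(tab) < 2 || any(tab < 2)) {
    stop(sprintf("ANOVA needs >= 2 phases with >= 2 observations each (got: %s)",
                 paste(names(tab), tab, sep = "=", collapse = ", ")), call. = FALSE)
  }
  d$phase <- droplevels(d$phase)
  fit <- stats::aov(value ~ phase, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$phase
  structure(list(fit = fit,
                 f_statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 df = unname(an[["Df"]]),
                 tukey = tibble::tibble(
                   pair = rownames(tk),
                   diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"],
                   significant = tk[, "p adj"] < alpha
                 ),
                 n = nrow(d), alpha = alpha),
            class = "egg_anova")
}

#' @export
print.egg_anova <- function(x, ...) {
  cat(sprintf("<egg_anova> F(%d, %d) = %.3g, p = %.3g (n = %d)\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value, x$n))
  print(x$tukey)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy egg_anova
#' @export
tidy.egg_anova <- function(x, ...) x$tukey

#' @method glance egg_anova
#' @export
glance.egg_anova <- function(x, ...) {
  tibble::tibble(statistic = x$f_statistic, p_value = x$p_value,
                 df = x$df[1], df_residual = x$df[2], n = x$n,
                 significant = x$p_value < x$alpha)
}

#' Linear regression of a feature on gestational age
#'
#' Ordinary least squares of a per-subject feature against gestational age
#' at birth, the trend test used for the maturity hypotheses (rising
#' during-feed band power, rising percent normogastria). When a subject
#' contributes several rows (repeated sessions), they are averaged per
#' subject first unless `per_session = TRUE`, to avoid pseudo-replication.
#'
#' @param data Data frame with columns `ga_weeks`, the feature in `value`,
#'   and (for the default averaging) `subject_id`.
#' @param value Name of the feature column (default `"value"`).
#' @param per_session Keep one point per row instead of averaging within
#'   subject (default `FALSE`).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `egg_ga_fit` wrapping the `lm` fit; `tidy()`
#'   gives the coefficient table, `glance()` the slope, r-squared, p-value
#'   and n.
#' @examples
#' d <- data.frame(subject_id = letters[1:10], ga_weeks = 25:34,
#'                 value = 2 * (25:34) + rnorm(10))
#' glance(regress_on_ga(d))
#' @export
regress_on_ga <- function(data, value = "value", per_session = FALSE,
                          alpha = 0.05) {
  stopifnot(value %in% names(data), "ga_weeks" %in% names(data))
  d <- data.frame(ga_weeks = data$ga_weeks, value = data[[value]],
                  subject_id = if ("subject_id" %in% names(data)) {
                    data$subject_id
                  } else {
                    seq_len(nrow(data))
                  })
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (!per_session) {
    d <- d |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(ga_weeks = .data$ga_weeks[1], value = mean(.data$value),
                       .groups = "drop")
  }
  if (nrow(d) < 3 || length(unique(d$ga_weeks)) < 3) {
    stop("regression needs at least 3 subjects with distinct gestational ages",
         call. = FALSE)
  }
  if (stats::sd(d$ga_weeks) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(value ~ ga_weeks, data = d)
  s <- summary(fit)
  structure(list(fit = fit, data = tibble::as_tibble(d),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_value = s$coefficients["ga_weeks", "Pr(>|t|)"],
                 n = nrow(d), alpha = alpha),
            class = "egg_ga_fit")
}

#' @export
print.egg_ga_fit <- function(x, ...) {
  cat(sprintf("<egg_ga_fit> slope = %.4g per week, r^2 = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @method tidy egg_ga_fit
#' @export
tidy.egg_ga_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
                 statistic = s[, 3], p_value = s[, 4])
}

#' @method glance egg_ga_fit
#' @export
glance.egg_ga_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, p_value = x$p_value, n = x$n,
                 significant = x$p_value < x$alpha)
}

#' ANOVA battery over a cohort feature table
#'
#' Runs [anova_phases()] for every gestational-age group x band x feature
#' cell of a cohort table, mirroring the within-group across-phase
#' comparison of the study design. Cells with too little data are reported
#' as unavailable rather than failing the whole battery.
#'
#' @param features Cohort feature table from [cohort_features()].
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per group x band x feature x phase-pair
#'   (Tukey contrasts), plus the omnibus F and p.
#' @export
anova_battery <- function(features, alpha = 0.05) {
  cells <- features |>
    dplyr::distinct(.data$ga_group, .data$band, .data$feature)
  purrr::pmap_dfr(cells, function(ga_group, band, feature) {
    d <- features[features$ga_group == ga_group & features$band == band &
                    features$feature == feature, ]
    res <- tryCatch(anova_phases(d, alpha = alpha), error = function(e) NULL)
    base <- tibble::tibble(ga_group = ga_group, band = band, feature = feature)
    if (is.null(res)) {
      return(dplyr::mutate(base, f_statistic = NA_real_, p_value = NA_real_,
                           pair = NA_character_, diff = NA_real_,
                           p_adj = NA_real_, significant = NA,
                           available = FALSE))
    }
    pairs <- tidy(res)[, c("pair", "diff", "p_adj", "significant")]
    dplyr::bind_cols(base[rep(1, nrow(pairs)), ],
                     tibble::tibble(f_statistic = res$f_statistic,
                                    p_value = res$p_value),
                     pairs) |>
      dplyr::mutate(available = TRUE)
  })
}

#' Regression battery over a cohort feature table
#'
#' Runs [regress_on_ga()] for every phase x band x feature cell, the
#' trend-versus-gestational-age analysis of the study design.
#'
#' @param features Cohort feature table from [cohort_features()].
#' @param alpha Significance level (default 0.05).
#' @param per_session Passed to [regress_on_ga()].
#' @return Tibble with one row per phase x band x feature: slope,
#'   r-squared, p-value, n, significance flag.
#' @export
regression_battery <- function(features, alpha = 0.05, per_session = FALSE) {
  cells <- features |>
    dplyr::distinct(.data$phase, .data$band, .data$feature)
  purrr::pmap_dfr(cells, function(phase, band, feature) {
    d <- features[features$phase == phase & features$band == band &
                    features$feature == feature, ]
    res <- tryCatch(regress_on_ga(d, alpha = alpha, per_session = per_session),
                    error = function(e) NULL)
    base <- tibble::tibble(phase = phase, band = band, feature = feature)
    if (is.null(res)) {
      return(dplyr::mutate(base, slope = NA_real_, r_squared = NA_real_,
                           p_value = NA_real_, n = NA_integer_,
                           significant = NA, available = FALSE))
    }
    dplyr::mutate(base, slope = res$slope, r_squared = res$r_squared,
                  p_value = res$p_value, n = res$n,
                  significant = res$p_value < res$alpha, available = TRUE)
  })
}
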