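#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Welch power spectral density over the gastric range
#'
#' @param object An `egg_psd` from [welch_psd()].
#' @param max_cpm Upper frequency limit of the plot in cpm (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot egg_psd
#' @export
autoplot.egg_psd <- function(object, max_cpm = 10, ...) {
  bands <- gastric_bands()
  d <- dplyr::filter(tibble::as_tibble(object), .data$freq_cpm <= max_cpm)
  ggplot2::ggplot(d, ggplot2::aes(.data$freq_cpm, .data$psd)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(bands$lo_cpm, max(bands$hi_cpm)),
                        colour = "red", linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "Frequency (cpm)",
                  y = expression(PSD ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
}

#' Plot a CWT spectrogram with its cone of influence
#'
#' @param object An `egg_cwt` from [cwt_power()].
#' @param max_cpm Upper frequency limit in cpm (default 10).
#' @param ... Unused.
#' @return A ggplot; COI-masked cells are greyed out.
#' @method autoplot egg_cwt
#' @export
autoplot.egg_cwt <- function(object, max_cpm = 10, ...) {
  sel <- object$freq_cpm <= max_cpm
  d <- tidyr::expand_grid(freq_cpm = object$freq_cpm[sel],
                          time_min = object$time_s / 60)
  d$power <- as.vector(t(object$power[sel, , drop = FALSE]))
  d$power <- replace(d$power, as.vector(t(object$coi[sel, , drop = FALSE])), NA)
  bands <- gastric_bands()
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$freq_cpm,
                                  fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = c(bands$lo_cpm, max(bands$hi_cpm)),
                        colour = "white", linetype = 3, linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey70") +
    ggplot2::labs(x = "Time (min)", y = "Frequency (cpm)", fill = "Power") +
    ggplot2::theme_minimal()
}

#' Dominant-rhythm partition map
#'
#' One tile per minute at the dominant band's row -- the minute-by-minute
#' partition of the recording into bradygastria, normogastria and
#' tachygastria.
#'
#' @param partition A tibble from [minute_band_ratios()].
#' @return A ggplot.
#' @export
plot_partition_map <- function(partition) {
  d <- dplyr::filter(partition, !is.na(.data$dominant))
  ggplot2::ggplot(d, ggplot2::aes(.data$minute + 0.5, .data$dominant)) +
    ggplot2::geom_tile(fill = "red", colour = "grey30",
                       width = 1, height = 0.9) +
    ggplot2::scale_y_discrete(limits = band_levels(), drop = FALSE) +
    ggplot2::labs(x = "Time (min)", y = "Gastric rhythm band") +
    ggplot2::theme_minimal()
}

#' Scatter and fitted line for a gestational-age regression
#'
#' @param object An `egg_ga_fit` from [regress_on_ga()].
#' @param ... Unused.
#' @return A ggplot of the per-subject feature against gestational age with
#'   the least-squares line and its fit annotation.
#' @method autoplot egg_ga_fit
#' @export
autoplot.egg_ga_fit <- function(object, ...) {
  g <- glance(object)
  lab <- sprintf("slope = %.3g/week, r2 = %.2f, p = %.2g",
                 g$slope, g$r_squared, g$p_value)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$ga_weeks, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::labs(x = "Gestational age (weeks)", y = "Feature value",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}
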