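# Plot helpers for the main result types.

#' Plot stratified CAP triggering rates
#'
#' Bar chart of any-level triggering rates by protocol and stratum
#' (the qualitative display used to compare homeless and non-homeless
#' safety-protocol rates across settings).
#'
#' @param rates Tibble from [triggering_rates()].
#' @return A ggplot object.
#' @export
plot_triggering_rates <- function(rates) {
  any_rows <- rates[is.na(rates$level), , drop = FALSE]
  ggplot2::ggplot(any_rows,
                  ggplot2::aes(x = .data$cap, y = .data$rate,
                               fill = factor(.data$stratum))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "triggering rate", fill = "stratum") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Plot a quality-indicator trend
#'
#' Risk-adjusted indicator rates over periods, one line per stratum.
#'
#' @param trend Tibble from [qi_trend()].
#' @param stratum Optional name of a stratum column for line grouping.
#' @return A ggplot object.
#' @export
plot_qi_trend <- function(trend, stratum = NULL) {
  aes <- if (is.null(stratum)) {
    ggplot2::aes(x = .data$period, y = .data$adjusted_rate)
  } else {
    ggplot2::aes(x = .data$period, y = .data$adjusted_rate,
                 colour = factor(.data[[stratum]]),
                 group = factor(.data[[stratum]]))
  }
  ggplot2::ggplot(trend, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "period", y = "risk-adjusted rate", colour = stratum) +
    ggplot2::theme_minimal()
}

#' Plot a case-mix index trend
#'
#' Mean CMI with 95\% confidence band by period, one line per assessment
#' reason (admission vs discharge).
#'
#' @param trend Tibble from [summarize_cmi_trend()].
#' @return A ggplot object.
#' @export
plot_cmi_trend <- function(trend) {
  ggplot2::ggplot(trend,
                  ggplot2::aes(x = .data$period, y = .data$mean_cmi,
                               colour = .data$reason, group = .data$reason)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                                      fill = .data$reason), alpha = 0.15,
                         colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "period", y = "mean case-mix index") +
    ggplot2::theme_minimal()
}

#' Forest plot of a convergent-validity fit
#'
#' Odds ratios (log scale) with 95\% intervals per covariate band.
#'
#' @param object An `mh_validity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mh_validity <- function(object, ...) {
  td <- tidy(object)
  td$term <- paste(td$covariate, td$band)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
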