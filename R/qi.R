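# Mental-health quality indicators (MHQIs).
#
# Two outcome families over admission -> follow-up scale pairs:
#   improvement: among persons with a non-zero baseline score,
#                follow-up < baseline;
#   failure:     among persons below the scale maximum at baseline,
#                follow-up >= baseline (worsening or failure to improve;
#                a strict-worsening variant uses follow-up > baseline).
# The follow-up is the earliest reassessment within 90 days of admission,
# or the discharge assessment if discharge came first.  Risk adjustment is
# indirect standardization against a pooled logistic model.

#' Pair admissions with follow-up assessments
#'
#' Walks each person's assessments in date order, opens an episode at
#' each admission, and pairs it with the earliest subsequent review or
#' discharge assessment no more than `window` days later (inclusive day
#' counting).  Admissions with no eligible follow-up are excluded and
#' counted in the `excluded` attribute; non-monotone episodes (a
#' follow-up dated before its admission) are skipped with a log entry.
#' Both assessments are scored on the requested scale.
#'
#' @param records Longitudinal tibble of assessment records (needs
#'   `person_id`, `reason`, `date`).
#' @param scale Scale name to score (one of [scale_definitions()]).
#' @param registry An `mh_registry`.
#' @param window Maximum days from admission to follow-up (default 90).
#' @param covariates Covariate columns to carry from the admission record.
#' @return A tibble of QI pairs: `person_id`, `scale`, `baseline`,
#'   `followup`, `baseline_date`, `followup_date`, `followup_reason`,
#'   `period` (admission year) and the requested covariates, with
#'   attribute `excluded` (a tibble of unpaired/skipped admissions).
#' @export
pair_followups <- function(records, scale, registry = mh_registry(),
                           window = 90L,
                           covariates = intersect(c("age", "sex", "homeless"),
                                                  names(records))) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("person_id", "reason", "date") %in% names(records)))
  defs <- scale_definitions(extras = TRUE)
  if (!scale %in% names(defs)) stop("unknown scale: ", scale, call. = FALSE)
  def <- defs[[scale]]
  sc <- if (def$kind == "sum") {
    score_sum_scale(records, def, registry)
  } else {
    score_tree_scale(records, def, registry)
  }
  # records are walked in the order given per person (chronological
  # expected); a follow-up dated before its admission marks the episode
  # as non-monotone and it is skipped with a log entry
  pid_v <- as.character(records$person_id)
  reason_v <- as.character(records$reason)
  date_v <- records$date
  value_v <- sc$value
  groups <- split(seq_along(pid_v), pid_v)

  cap <- length(pid_v)
  adm_i <- integer(cap); fu_i <- integer(cap); np <- 0L
  ex_i <- integer(cap); ex_why <- character(cap); nx <- 0L
  for (g in groups) {
    adm_pos <- which(reason_v[g] == "admission")
    for (j in seq_along(adm_pos)) {
      a <- adm_pos[j]
      ep_end <- if (j < length(adm_pos)) adm_pos[j + 1L] - 1L else length(g)
      ep <- if (a < ep_end) g[(a + 1L):ep_end] else integer()
      cand <- ep[reason_v[ep] %in% c("review", "discharge")]
      adm_date <- date_v[g[a]]
      if (length(cand) && any(date_v[cand] < adm_date)) {
        nx <- nx + 1L; ex_i[nx] <- g[a]; ex_why[nx] <- "non_monotone_dates"
        next
      }
      cand <- cand[as.integer(date_v[cand] - adm_date) <= window]
      if (!length(cand)) {
        nx <- nx + 1L; ex_i[nx] <- g[a]; ex_why[nx] <- "no_followup_in_window"
        next
      }
      f <- cand[which.min(as.integer(date_v[cand] - adm_date))]
      np <- np + 1L; adm_i[np] <- g[a]; fu_i[np] <- f
    }
  }
  adm_i <- adm_i[seq_len(np)]; fu_i <- fu_i[seq_len(np)]
  ex_i <- ex_i[seq_len(nx)]; ex_why <- ex_why[seq_len(nx)]
  out <- tibble::tibble(
    person_id = pid_v[adm_i], scale = scale,
    baseline = value_v[adm_i], followup = value_v[fu_i],
    baseline_date = date_v[adm_i], followup_date = date_v[fu_i],
    followup_reason = reason_v[fu_i],
    period = as.integer(format(date_v[adm_i], "%Y"))
  )
  for (cv in covariates) out[[cv]] <- records[[cv]][adm_i]
  attr(out, "excluded") <- tibble::tibble(
    person_id = pid_v[ex_i], date = date_v[ex_i], why = ex_why)
  out
}

qi_scale_max <- function(scale) {
  defs <- scale_definitions(extras = TRUE)
  if (!scale %in% names(defs)) stop("unknown scale: ", scale, call. = FALSE)
  defs[[scale]]$out_max
}

qi_eligible_event <- function(pairs, indicator, strict_worsening = FALSE) {
  smax <- qi_scale_max(pairs$scale[1])
  ok <- !is.na(pairs$baseline) & !is.na(pairs$followup)
  if (indicator == "improvement") {
    eligible <- ok & pairs$baseline > 0L
    event <- eligible & pairs$followup < pairs$baseline
  } else {
    eligible <- ok & pairs$baseline < smax
    event <- if (strict_worsening) {
      eligible & pairs$followup > pairs$baseline
    } else {
      eligible & pairs$followup >= pairs$baseline
    }
  }
  list(eligible = eligible, event = event)
}

#' Compute raw quality-indicator rates
#'
#' Applies one of the two outcome definitions to a set of QI pairs for a
#' single scale and reports numerator, denominator and rate, overall or
#' per stratum.
#'
#' @param pairs QI pairs from [pair_followups()] (one scale only).
#' @param indicator `"improvement"` or `"failure"`.
#' @param by Optional stratifying column name(s).
#' @param strict_worsening For the failure indicator, count only strict
#'   worsening (`followup > baseline`) as an event.
#' @return Tibble: strata columns (if any), `indicator`, `scale`,
#'   `numerator`, `denominator`, `rate` (`NaN` when the denominator is 0).
#' @export
compute_qi <- function(pairs, indicator = c("improvement", "failure"),
                       by = NULL, strict_worsening = FALSE) {
  indicator <- match.arg(indicator)
  pairs <- tibble::as_tibble(pairs)
  stopifnot(nrow(pairs) == 0L || length(unique(pairs$scale)) == 1L)
  if (!nrow(pairs)) {
    return(tibble::tibble(indicator = character(), scale = character(),
                          numerator = integer(), denominator = integer(),
                          rate = double()))
  }
  ee <- qi_eligible_event(pairs, indicator, strict_worsening)
  pairs$.eligible <- ee$eligible
  pairs$.event <- ee$event
  grouped <- if (is.null(by)) pairs else
    dplyr::group_by(pairs, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grouped,
    indicator = indicator, scale = pairs$scale[1],
    numerator = sum(.data$.event), denominator = sum(.data$.eligible),
    rate = sum(.data$.event) / sum(.data$.eligible),
    .groups = "drop"
  )
  tibble::as_tibble(out)
}

#' Risk-adjusted quality indicators (indirect standardization)
#'
#' Fits a logistic model of the indicator event on baseline covariates
#' over the pooled eligible pairs, computes each stratum's expected rate
#' as the mean fitted probability of its members, and reports
#' adjusted = (observed / expected) x pooled rate, clipped to \[0, 1\]
#' with a flag when clipping occurs.  With an intercept-only model
#' (`covariates = character()`) the adjusted rate equals the observed
#' rate.  If the pooled sample has no events (or no non-events) the model
#' is degenerate and the adjusted rate falls back to the observed rate
#' with a warning.
#'
#' @param pairs QI pairs from [pair_followups()].
#' @param indicator `"improvement"` or `"failure"`.
#' @param by Stratifying column name(s).
#' @param covariates Baseline covariate columns for the risk model
#'   (default: whichever of age band, sex, homeless and baseline score
#'   band are present; `.age_band` and `.baseline_band` are derived
#'   automatically from `age` and `baseline`).
#' @param strict_worsening See [compute_qi()].
#' @return Tibble: strata columns, `indicator`, `scale`, `numerator`,
#'   `denominator`, `observed_rate`, `expected_rate`, `adjusted_rate`,
#'   `clipped`.
#' @export
risk_adjust <- function(pairs, indicator = c("improvement", "failure"),
                        by, covariates = NULL, strict_worsening = FALSE) {
  indicator <- match.arg(indicator)
  pairs <- tibble::as_tibble(pairs)
  stopifnot(length(unique(pairs$scale)) == 1L)
  pairs$.baseline_band <- cut(pairs$baseline,
                              breaks = c(-Inf, 0, 3, 7, Inf), right = TRUE,
                              labels = c("0", "1-3", "4-7", "8+"))
  if ("age" %in% names(pairs)) {
    pairs$.age_band <- cut(pairs$age, breaks = c(-Inf, 24, 44, 64, Inf),
                           labels = c("18-24", "25-44", "45-64", "65+"))
  }
  if (is.null(covariates)) {
    covariates <- intersect(c(".age_band", "sex", "homeless", ".baseline_band"),
                            names(pairs))
  }
  ee <- qi_eligible_event(pairs, indicator, strict_worsening)
  el <- pairs[ee$eligible, , drop = FALSE]
  el$.event <- ee$event[ee$eligible]
  if (!nrow(el)) stop("no eligible pairs", call. = FALSE)
  cc <- stats::complete.cases(el[, covariates, drop = FALSE])
  n_dropped <- sum(!cc)
  el <- el[cc, , drop = FALSE]

  pooled_rate <- mean(el$.event)
  degenerate <- pooled_rate %in% c(0, 1)
  if (length(covariates) == 0L || degenerate) {
    if (degenerate) {
      warning("degenerate risk model (no events or no non-events); ",
              "adjusted = observed", call. = FALSE)
    }
    el$.expected <- pooled_rate
  } else {
    f <- stats::as.formula(paste(".event ~", paste(covariates, collapse = " + ")))
    fit <- stats::glm(f, data = el, family = stats::binomial())
    el$.expected <- stats::fitted(fit)
  }

  out <- el |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      indicator = indicator, scale = el$scale[1],
      numerator = sum(.data$.event), denominator = dplyr::n(),
      observed_rate = mean(.data$.event),
      expected_rate = mean(.data$.expected),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      adjusted_rate = .data$observed_rate / .data$expected_rate * pooled_rate,
      clipped = .data$adjusted_rate > 1 | .data$adjusted_rate < 0,
      adjusted_rate = pmin(pmax(.data$adjusted_rate, 0), 1)
    )
  attr(out, "n_dropped") <- n_dropped
  attr(out, "pooled_rate") <- pooled_rate
  tibble::as_tibble(out)
}

#' Quality-indicator trend table
#'
#' Risk-adjusted indicator rates by period (and any further strata),
#' suitable for plotting temporal trends.
#'
#' @param pairs QI pairs from [pair_followups()].
#' @param indicator `"improvement"` or `"failure"`.
#' @param by Stratifying columns; default `"period"` (add e.g.
#'   `"homeless"` for subgroup series).
#' @param ... Passed to [risk_adjust()].
#' @return Tibble as from [risk_adjust()], arranged by period.
#' @export
qi_trend <- function(pairs, indicator = c("improvement", "failure"),
                     by = "period", ...) {
  indicator <- match.arg(indicator)
  out <- risk_adjust(pairs, indicator, by = by, ...)
  dplyr::arrange(out, dplyr::across(dplyr::all_of(by)))
}
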