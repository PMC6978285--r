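# Per-diem case-mix: group assignment, case-mix indexes (CMIs), trends.
#
# The published inpatient-psychiatry case-mix system (SCIPP, 47 groups,
# ~100 variables, an 8.4:1 CMI spread) is proprietary and unpublished;
# this module supplies the surrounding machinery — a pluggable grouping
# function, CMI application and admission/discharge trend summaries —
# together with a documented toy grouper for demonstrations and tests.

#' Construct a CMI table
#'
#' @param groups Character vector of case-mix group labels, or a data
#'   frame with columns `group` and `cmi` (e.g. read from CSV).
#' @param cmi Positive case-mix index per group (ratio scale).
#' @return A tibble of class `mh_cmi_table` with columns `group`, `cmi`,
#'   and attribute `spread` = max(cmi)/min(cmi).
#' @export
cmi_table <- function(groups, cmi = NULL) {
  if (is.data.frame(groups)) {
    df <- tibble::as_tibble(groups)
    stopifnot(all(c("group", "cmi") %in% names(df)))
  } else {
    df <- tibble::tibble(group = as.character(groups), cmi = as.numeric(cmi))
  }
  if (anyDuplicated(df$group)) stop("duplicate group labels", call. = FALSE)
  if (any(!is.finite(df$cmi) | df$cmi <= 0)) {
    stop("all CMIs must be positive", call. = FALSE)
  }
  attr(df, "spread") <- max(df$cmi) / min(df$cmi)
  class(df) <- c("mh_cmi_table", class(df))
  df
}

#' CMI spread (max/min ratio)
#' @param table An `mh_cmi_table`.
#' @return The ratio of the largest to the smallest CMI.
#' @export
cmi_spread <- function(table) max(table$cmi) / min(table$cmi)

#' Default demonstration CMI table
#'
#' Six groups spanning the published 8.4:1 spread of per-diem resource
#' intensity (0.5 to 4.2); values are illustrative, not the proprietary
#' weights.
#' @return An `mh_cmi_table`.
#' @export
default_cmi_table <- function() {
  cmi_table(
    c("low_need", "moderate", "depressive", "psychotic", "behavioral", "acute_complex"),
    c(0.5, 0.8, 1.1, 1.6, 2.6, 4.2)
  )
}

#' Toy case-mix grouper
#'
#' A documented demonstration classifier over scored records: assigns one
#' of the six [default_cmi_table()] groups from the Cognitive Performance,
#' Positive Symptoms, Aggressive Behavior, Severity of Self-harm and
#' Depressive Severity scales.  Deterministic and total over records with
#' those scores; records missing a needed score are unassignable.
#'
#' @param scores Wide tibble with columns `cps`, `pss`, `abs`, `sss`, `dsi`.
#' @return Character vector of group labels (`NA` where unassignable).
#' @export
toy_grouper <- function(scores) {
  need <- c("cps", "pss", "abs", "sss", "dsi")
  for (v in need) if (!v %in% names(scores)) {
    stop("toy grouper needs score column '", v, "'", call. = FALSE)
  }
  with(scores, dplyr::case_when(
    is.na(cps) | is.na(pss) | is.na(abs) | is.na(sss) | is.na(dsi) ~ NA_character_,
    sss >= 5 | (pss >= 9 & abs >= 9) ~ "acute_complex",
    abs >= 8 ~ "behavioral",
    pss >= 7 ~ "psychotic",
    dsi >= 8 ~ "depressive",
    cps >= 2 | dsi >= 4 | pss >= 3 ~ "moderate",
    TRUE ~ "low_need"
  ))
}

#' Assign case-mix groups and CMIs
#'
#' Scores the records (unless `scores` are supplied), applies the
#' grouping function and attaches each record's CMI.  Records the
#' grouper cannot classify are excluded from the result and logged in
#' the `excluded` attribute; a group label missing from the CMI table is
#' an error naming the label.
#'
#' @param records Tibble of assessment records.
#' @param grouper Function mapping a wide score tibble to group labels
#'   (default [toy_grouper()]).
#' @param table An `mh_cmi_table` (default [default_cmi_table()]).
#' @param registry An `mh_registry`.
#' @param scores Optional pre-computed wide score tibble aligned with
#'   `records`.
#' @return Tibble: record id columns (plus `period` when a date exists)
#'   and `group`, `cmi`; attribute `excluded` counts unassignable records.
#' @export
apply_cmi <- function(records, grouper = toy_grouper,
                      table = default_cmi_table(),
                      registry = mh_registry(), scores = NULL) {
  records <- tibble::as_tibble(records)
  if (is.null(scores)) {
    scores <- scores_to_wide(score_scales(records, registry), records)
  }
  group <- as.character(grouper(scores))
  stopifnot(length(group) == nrow(records))
  unknown <- setdiff(stats::na.omit(unique(group)), table$group)
  if (length(unknown)) {
    stop("group label(s) not in CMI table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- records[, score_id_cols(records), drop = FALSE]
  if ("date" %in% names(out)) {
    out$period <- as.integer(format(out$date, "%Y"))
  }
  out$group <- group
  out$cmi <- table$cmi[match(group, table$group)]
  excluded <- sum(is.na(group))
  out <- out[!is.na(group), , drop = FALSE]
  attr(out, "excluded") <- excluded
  tibble::as_tibble(out)
}

#' Summarize CMI trends
#'
#' Mean CMI with a normal-approximation 95\% confidence interval and cell
#' size by assessment reason and period.
#'
#' @param assignments Tibble from [apply_cmi()] with `reason` and
#'   `period` columns.
#' @param by Grouping columns (default reason and period).
#' @return Tibble: grouping columns, `n`, `mean_cmi`, `ci_low`, `ci_high`.
#' @export
summarize_cmi_trend <- function(assignments, by = c("reason", "period")) {
  assignments <- tibble::as_tibble(assignments)
  z <- stats::qnorm(0.975)
  assignments |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cmi = mean(.data$cmi),
      se = stats::sd(.data$cmi) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(ci_low = .data$mean_cmi - z * .data$se,
                  ci_high = .data$mean_cmi + z * .data$se) |>
    dplyr::select(-"se") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)))
}

#' Percent change between two period means
#'
#' The trend arithmetic used for case-mix reporting:
#' 100 x (later - earlier) / earlier, displayed to one decimal.  Note the
#' definition is anchored on the earlier value: swapping the arguments
#' changes the denominator, not just the sign.
#'
#' @param earlier,later Mean values for the earlier and later period.
#' @param digits Decimal places for the display value (default 1).
#' @return A list with `change` (exact) and `display` (rounded).
#' @export
#' @examples
#' cmi_percent_change(1.567, 1.657)$display  # 5.7
cmi_percent_change <- function(earlier, later, digits = 1) {
  stopifnot(is.finite(earlier), is.finite(later), earlier != 0)
  change <- (later - earlier) / earlier * 100
  list(change = change, display = round(change, digits))
}
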