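# Clinical Assessment Protocol (CAP) triggers.
#
# The protocol list, grouping, level counts and instrument applicability
# reproduce the published matrix (21 protocols; the inpatient and
# community instruments each trigger 20 — they differ only on Informal
# Support vs Support Systems for Discharge — and the emergency screener
# triggers the three safety protocols plus Smoking).  The trigger
# thresholds themselves are unpublished; the rules shipped here are
# documented, non-canonical defaults expressed as declarative predicates
# over items and scale scores, monotone in their inputs, with level 2
# tested before level 1.

cap_rule <- function(var, value) list(var = var, value = value)

#' Shipped CAP definitions
#'
#' One row per protocol with its group, number of trigger levels,
#' instrument applicability and default level rules.  A level rule is a
#' conjunction of `var >= value` conditions over item codes and scale
#' names; the triggered level is the highest level whose rule holds.
#'
#' @return A tibble with columns `cap`, `group`, `n_levels`, `mh`, `cmh`,
#'   `esp` (logical applicability) and `rules` (list column: per level,
#'   outermost = highest level, a list of conditions).
#' @export
cap_definitions <- function() {
  tibble::tribble(
    ~cap,                         ~group,            ~n_levels, ~mh,  ~cmh,  ~esp,  ~rules,
    "harm_to_others",             "safety",          2L, TRUE,  TRUE,  TRUE,
      list(l2 = list(cap_rule("rho", 4L)), l1 = list(cap_rule("rho", 1L))),
    "suicidality_self_harm",      "safety",          2L, TRUE,  TRUE,  TRUE,
      list(l2 = list(cap_rule("sss", 4L)), l1 = list(cap_rule("sss", 1L))),
    "self_care",                  "safety",          2L, TRUE,  TRUE,  TRUE,
      list(l2 = list(cap_rule("sci", 4L)), l1 = list(cap_rule("sci", 1L))),
    "social_relationships",       "social life",     2L, TRUE,  TRUE,  FALSE,
      list(l2 = list(cap_rule("sws", 9L)), l1 = list(cap_rule("sws", 5L))),
    "informal_support",           "social life",     2L, FALSE, TRUE,  FALSE,
      list(l2 = list(cap_rule("informal_support_problem", 2L)),
           l1 = list(cap_rule("informal_support_problem", 1L))),
    "support_systems_discharge",  "social life",     1L, TRUE,  FALSE, FALSE,
      list(l1 = list(cap_rule("lack_of_discharge_support", 1L))),
    "interpersonal_conflict",     "social life",     2L, TRUE,  TRUE,  FALSE,
      list(l2 = list(cap_rule("conflict_with_others", 2L)),
           l1 = list(cap_rule("conflict_with_others", 1L))),
    "traumatic_life_events",      "social life",     2L, TRUE,  TRUE,  FALSE,
      list(l2 = list(cap_rule("recent_trauma", 1L)),
           l1 = list(cap_rule("traumatic_event_fear", 2L))),
    "criminal_activity",          "social life",     1L, TRUE,  TRUE,  FALSE,
      list(l1 = list(cap_rule("violence_extreme_behavior", 2L))),
    "personal_finances",          "economic issues", 2L, TRUE,  TRUE,  FALSE,
      list(l2 = list(cap_rule("economic_hardship", 2L)),
           l1 = list(cap_rule("economic_hardship", 1L))),
    "education_employment",       "economic issues", 2L, TRUE,  TRUE,  FALSE,
      list(l2 = list(cap_rule("education_employment_risk", 2L)),
           l1 = list(cap_rule("education_employment_risk", 1L))),
    "control_interventions",      "autonomy",        2L, TRUE,  TRUE,  FALSE,
      list(l2 = list(cap_rule("control_intervention_history", 2L)),
           l1 = list(cap_rule("control_intervention_history", 1L))),
    "medication_management",      "autonomy",        2L, TRUE,  TRUE,  FALSE,
      list(l2 = list(cap_rule("stopped_meds", 1L)),
           l1 = list(cap_rule("med_adherence_problem", 1L))),
    "rehospitalization",          "autonomy",        2L, TRUE,  TRUE,  FALSE,
      list(l2 = list(cap_rule("prior_hospitalizations", 3L)),
           l1 = list(cap_rule("prior_hospitalizations", 1L))),
    "smoking",                    "health promotion", 2L, TRUE, TRUE,  TRUE,
      list(l2 = list(cap_rule("withdrawal_symptoms", 2L)),
           l1 = list(cap_rule("smokes_daily", 1L))),
    "substance_use",              "health promotion", 2L, TRUE, TRUE,  FALSE,
      list(l2 = list(cap_rule("cage", 2L)), l1 = list(cap_rule("cage", 1L))),
    "weight_management",          "health promotion", 2L, TRUE, TRUE,  FALSE,
      list(l2 = list(cap_rule("bmi_problem", 1L)),
           l1 = list(cap_rule("eating_behavior", 1L))),
    "exercise",                   "health promotion", 2L, TRUE, TRUE,  FALSE,
      list(l2 = list(cap_rule("low_physical_activity", 2L)),
           l1 = list(cap_rule("low_physical_activity", 1L))),
    "sleep_disturbance",          "health promotion", 2L, TRUE, TRUE,  FALSE,
      list(l2 = list(cap_rule("sleep_disturbance", 2L), cap_rule("cps", 1L)),
           l1 = list(cap_rule("sleep_disturbance", 1L))),
    "pain",                       "health promotion", 2L, TRUE, TRUE,  FALSE,
      list(l2 = list(cap_rule("pain", 3L)), l1 = list(cap_rule("pain", 1L))),
    "falls",                      "health promotion", 2L, TRUE, TRUE,  FALSE,
      list(l2 = list(cap_rule("falls", 2L)), l1 = list(cap_rule("falls", 1L)))
  )
}

cap_rule_vars <- function(rules) {
  unique(unlist(lapply(rules, function(lvl) vapply(lvl, `[[`, "", "var"))))
}

#' Evaluate CAP triggers
#'
#' Evaluates every applicable protocol on each record and returns the
#' triggered level (0 = not triggered).  Levels are tested top-down: the
#' result is the highest level whose rule conjunction holds.  Conditions
#' touching missing inputs evaluate as not-satisfied and are reflected in
#' `inputs_complete`.
#'
#' @param records Tibble of assessment records.
#' @param registry An `mh_registry`.
#' @param defs CAP definitions, default [cap_definitions()].
#' @param scores Optional pre-computed wide score table (one column per
#'   scale, rows aligned with `records`); computed via [score_scales()]
#'   when omitted.
#' @return Long tibble: id columns plus `cap`, `group`, `level`,
#'   `n_levels`, `inputs_complete`.
#' @export
evaluate_caps <- function(records, registry = mh_registry(),
                          defs = cap_definitions(), scores = NULL) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  scale_defs <- scale_definitions(extras = TRUE)
  # config check: a rule referencing a scale unavailable on an applicable
  # instrument is a definition error, raised before any scoring
  for (i in seq_len(nrow(defs))) {
    vars <- cap_rule_vars(defs$rules[[i]])
    for (ins in c("MH", "CMH", "ESP")) {
      if (!defs[[tolower(ins)]][i]) next
      for (v in intersect(vars, names(scale_defs))) {
        if (!ins %in% scale_defs[[v]]$instruments) {
          stop(sprintf("CAP '%s' references scale '%s', unavailable on %s",
                       defs$cap[i], v, ins), call. = FALSE)
        }
      }
    }
  }
  if (is.null(scores)) {
    # score the full definition set so tree scales find their sub-scales
    scores_long <- score_scales(records, registry, defs = scale_defs)
    scores <- scores_to_wide(scores_long, records)
  }
  pieces <- list()
  for (ins in unique(records$instrument)) {
    ins_ok <- match_instrument(ins)
    col <- tolower(ins_ok)
    idx <- which(records$instrument == ins)
    sub <- records[idx, , drop = FALSE]
    sub_scores <- scores[idx, , drop = FALSE]
    applicable <- if (col %in% c("mh", "cmh", "esp")) defs[defs[[col]], ] else defs[0, ]
    for (j in seq_len(nrow(applicable))) {
      rules <- applicable$rules[[j]]  # listed highest level first
      level <- rep(0L, nrow(sub))
      complete <- rep(TRUE, nrow(sub))
      for (k in seq_along(rules)) {
        this_level <- length(rules) - k + 1L
        sat <- rep(TRUE, nrow(sub))
        for (cond in rules[[k]]) {
          v <- lookup_cap_var(cond$var, sub, sub_scores)
          complete <- complete & !is.na(v)
          sat <- sat & !is.na(v) & v >= cond$value
        }
        level <- pmax(level, ifelse(sat, this_level, 0L))
      }
      out <- sub[, score_id_cols(sub), drop = FALSE]
      out$cap <- applicable$cap[j]
      out$group <- applicable$group[j]
      out$level <- level
      out$n_levels <- applicable$n_levels[j]
      out$inputs_complete <- complete
      pieces[[paste(ins, applicable$cap[j])]] <- tibble::as_tibble(out)
    }
  }
  if (!length(pieces)) {
    return(tibble::tibble(person_id = character(), cap = character(),
                          group = character(), level = integer(),
                          n_levels = integer(), inputs_complete = logical()))
  }
  dplyr::bind_rows(pieces)
}

lookup_cap_var <- function(var, records, scores) {
  if (!is.null(scores) && var %in% names(scores)) return(scores[[var]])
  if (var %in% names(records)) return(records[[var]])
  rep(NA_integer_, nrow(records))
}

# Pivot a long score table to one column per scale, aligned with records.
scores_to_wide <- function(scores_long, records) {
  n <- nrow(records)
  out <- tibble::tibble(.rows = n)
  if (!nrow(scores_long)) return(out)
  key_cols <- intersect(score_id_cols(records), names(scores_long))
  rec_key <- do.call(paste, c(records[key_cols], sep = "\r"))
  for (s in unique(scores_long$scale)) {
    sub <- scores_long[scores_long$scale == s, , drop = FALSE]
    sub_key <- do.call(paste, c(sub[key_cols], sep = "\r"))
    out[[s]] <- sub$value[match(rec_key, sub_key)]
  }
  out
}

#' Stratified CAP triggering rates
#'
#' Summarizes CAP results as triggered-at-level proportions within strata
#' of a covariate.  Rates are reported with numerator and denominator;
#' empty strata are undefined (`NaN`), never zero.
#'
#' @param results CAP results from [evaluate_caps()], joined with the
#'   stratifying covariate (e.g. via the source records).
#' @param stratifier Name of the stratifying column in `results`.
#' @return Tibble: `cap`, `stratum`, `level`, `n_triggered`, `n`, `rate`.
#'   Rows with an exact `level` give per-level rates; the `level = NA`
#'   rows aggregate any triggering (level >= 1).
#' @export
triggering_rates <- function(results, stratifier) {
  stopifnot(is.data.frame(results))
  if (!stratifier %in% names(results)) {
    stop("unknown stratifier: ", stratifier, call. = FALSE)
  }
  results <- tibble::as_tibble(results)
  results$stratum <- results[[stratifier]]
  base <- results |>
    dplyr::group_by(.data$cap, .data$stratum)
  per_level <- base |>
    dplyr::group_by(.data$level, .add = TRUE) |>
    dplyr::summarise(n_triggered = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(n = sum(.data$n_triggered),
                  rate = .data$n_triggered / .data$n) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$level > 0L)
  any_level <- base |>
    dplyr::summarise(n_triggered = sum(.data$level >= 1L),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(level = NA_integer_, rate = .data$n_triggered / .data$n)
  dplyr::bind_rows(per_level, any_level) |>
    dplyr::select("cap", "stratum", "level", "n_triggered", "n", "rate") |>
    dplyr::arrange(.data$cap, .data$stratum, .data$level)
}
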