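# Summary-scale engine: parallel-form sum scales and decision-tree scales.
#
# Scale definitions are data, not code.  Sum scales name their component
# items; tree scales additionally carry a declarative binary tree over item
# values and sub-scale scores with integer leaves in 0..6.  The published
# family names the four tree scales and their inputs but not the trees
# themselves, so the trees shipped here are documented defaults that
# realize the full 0-6 output range; they are replaceable by licensed
# specifications via `tree =` in the definition.

new_scale_def <- function(name, label, kind, components, instruments,
                          out_min, out_max, component_max = NULL,
                          subscales = character(), tree = NULL) {
  stopifnot(kind %in% c("sum", "decision_tree"))
  if (kind == "decision_tree") {
    stopifnot(!is.null(tree), out_min == 0L, out_max == 6L)
  }
  structure(
    list(name = name, label = label, kind = kind, components = components,
         instruments = instruments, out_min = as.integer(out_min),
         out_max = as.integer(out_max), component_max = component_max,
         subscales = subscales, tree = tree),
    class = "mh_scale_def"
  )
}

#' @export
print.mh_scale_def <- function(x, ...) {
  cat(sprintf("<mh_scale_def> %s (%s), range %d-%d, instruments: %s\n",
              x$name, x$kind, x$out_min, x$out_max,
              paste(x$instruments, collapse = "/")))
  invisible(x)
}

tree_leaf <- function(score) list(score = as.integer(score))
tree_node <- function(var, value, yes, no) {
  list(var = var, value = value, yes = yes, no = no)
}

# Default decision trees.  Conditions are all "var >= value"; `var` is an
# item code or the name of a declared sub-scale.

default_cps_tree <- function() {
  tree_node("daily_decision_making", 3L,
    tree_node("adl_eating", 3L, tree_leaf(6L), tree_leaf(5L)),
    tree_node("daily_decision_making", 2L,
      tree_node("short_term_memory", 1L, tree_leaf(4L), tree_leaf(3L)),
      tree_node("daily_decision_making", 1L,
        tree_node("short_term_memory", 1L, tree_leaf(3L), tree_leaf(2L)),
        tree_node("short_term_memory", 1L,
          tree_node("making_self_understood", 2L, tree_leaf(2L), tree_leaf(1L)),
          tree_node("making_self_understood", 2L, tree_leaf(1L), tree_leaf(0L))
        )
      )
    )
  )
}

default_rho_tree <- function() {
  tree_node("violence_extreme_behavior", 3L,
    tree_leaf(6L),
    tree_node("violence_extreme_behavior", 1L,
      tree_node("intimidation_threats", 2L, tree_leaf(5L), tree_leaf(4L)),
      tree_node("violent_ideation", 1L,
        tree_node("pss", 6L, tree_leaf(4L), tree_leaf(3L)),
        tree_node("intimidation_threats", 1L,
          tree_leaf(2L),
          tree_node("abs", 4L,
            tree_node("insight_problem", 1L, tree_leaf(2L), tree_leaf(1L)),
            tree_node("delusions", 2L,
              tree_leaf(1L),
              tree_node("sleep_disturbance", 3L, tree_leaf(1L), tree_leaf(0L))
            )
          )
        )
      )
    )
  )
}

default_sci_tree <- function() {
  tree_node("personal_hygiene", 3L,
    tree_node("cps", 2L, tree_leaf(6L), tree_leaf(5L)),
    tree_node("cps", 3L,
      tree_leaf(4L),
      tree_node("pss", 6L,
        tree_node("insight_problem", 1L, tree_leaf(4L), tree_leaf(3L)),
        tree_node("decreased_energy", 2L,
          tree_leaf(3L),
          tree_node("mania", 8L,
            tree_leaf(2L),
            tree_node("anhedonia", 2L,
              tree_node("making_self_understood", 2L, tree_leaf(2L), tree_leaf(1L)),
              tree_node("making_self_understood", 2L, tree_leaf(1L), tree_leaf(0L))
            )
          )
        )
      )
    )
  )
}

default_sss_tree <- function() {
  tree_node("suicide_attempts", 1L,
    tree_node("suicide_plan", 1L, tree_leaf(6L), tree_leaf(5L)),
    tree_node("suicide_plan", 1L,
      tree_node("self_harm_ideation", 1L, tree_leaf(5L), tree_leaf(4L)),
      tree_node("self_harm_ideation", 2L,
        tree_leaf(4L),
        tree_node("self_harm_ideation", 1L,
          tree_node("others_concerned", 1L, tree_leaf(4L), tree_leaf(3L)),
          tree_node("others_concerned", 1L,
            tree_node("dsi", 8L, tree_leaf(3L), tree_leaf(2L)),
            tree_node("dsi", 8L,
              tree_node("pss", 6L, tree_leaf(2L), tree_leaf(1L)),
              tree_node("cps", 4L, tree_leaf(1L), tree_leaf(0L))
            )
          )
        )
      )
    )
  )
}

#' Shipped scale definitions
#'
#' The thirteen summary scales of the adult mental-health suite: nine
#' parallel-form sum scales (Aggressive Behavior, ADL, Negative Symptoms,
#' CAGE-Crosswalk, Depressive Severity Index, IADL Capacity, Mania, PAIN,
#' Positive Symptoms) and four decision-tree scales (Cognitive Performance
#' Scale, Risk of Harm to Others, Self-Care Index, Severity of Self-harm),
#' each with its published output range and instrument applicability.
#'
#' The Aggressive Behavior Scale ships with range 0-12 (four items coded
#' 0-3, matching the analyzed distributions); `abs_variant = "0-8"` caps
#' each component at 2 to reproduce the alternative 0-8 form.  Setting
#' `extras = TRUE` appends the Social Withdrawal Scale (four items, 0-12),
#' which is used for banded convergent-validity analyses but is not part
#' of the core thirteen.
#'
#' @param abs_variant `"0-12"` (default) or `"0-8"`.
#' @param extras Append the Social Withdrawal Scale?
#' @return Named list of `mh_scale_def` objects.
#' @export
scale_definitions <- function(abs_variant = c("0-12", "0-8"), extras = FALSE) {
  abs_variant <- match.arg(abs_variant)
  mce <- c("MH", "CMH", "ESP")
  mc <- c("MH", "CMH")
  abs_def <- if (abs_variant == "0-12") {
    new_scale_def("abs", "Aggressive Behavior Scale", "sum",
                  c("verbal_abuse", "physical_abuse", "socially_inappropriate",
                    "resists_care"), mce, 0L, 12L)
  } else {
    new_scale_def("abs", "Aggressive Behavior Scale (0-8 variant)", "sum",
                  c("verbal_abuse", "physical_abuse", "socially_inappropriate",
                    "resists_care"), mce, 0L, 8L,
                  component_max = c(verbal_abuse = 2L, physical_abuse = 2L,
                                    socially_inappropriate = 2L, resists_care = 2L))
  }
  defs <- list(
    abs = abs_def,
    adl = new_scale_def("adl", "Activities of Daily Living Scale", "sum",
                        c("personal_hygiene", "locomotion", "toilet_use",
                          "adl_eating"), mc, 0L, 16L),
    negsym = new_scale_def("negsym", "Negative Symptoms Scale", "sum",
                           c("anhedonia", "withdrawal_from_activities",
                             "lack_of_motivation", "reduced_social_interactions"),
                           mce, 0L, 12L),
    cage = new_scale_def("cage", "CAGE-Crosswalk", "sum",
                         c("cage_cut_down", "cage_angered", "cage_guilt",
                           "cage_morning"), mc, 0L, 4L),
    cps = new_scale_def("cps", "Cognitive Performance Scale", "decision_tree",
                        c("daily_decision_making", "short_term_memory",
                          "making_self_understood", "adl_eating"),
                        mce, 0L, 6L, tree = default_cps_tree()),
    dsi = new_scale_def("dsi", "Depressive Severity Index", "sum",
                        c("sad_facial_expression", "negative_statements",
                          "self_deprecation", "guilt_shame", "hopelessness"),
                        mce, 0L, 15L),
    iadl = new_scale_def("iadl", "IADL Capacity Scale", "sum",
                         c("meal_preparation", "ordinary_housework",
                           "managing_finances", "managing_medications",
                           "phone_use", "shopping", "transportation"),
                         mc, 0L, 30L),
    mania = new_scale_def("mania", "Mania Scale", "sum",
                          c("inflated_self_worth", "hyperarousal", "irritability",
                            "increased_sociability", "pressured_speech",
                            "labile_affect", "sleep_problems_hypomania"),
                          mce, 0L, 20L),
    pain = new_scale_def("pain", "PAIN Scale", "sum",
                         c("pain_frequency", "pain_intensity"), mc, 0L, 4L),
    pss = new_scale_def("pss", "Positive Symptoms Scale", "sum",
                        c("hallucinations", "command_hallucinations",
                          "delusions", "abnormal_thought_process"),
                        c(mce, "BMHS"), 0L, 12L),
    rho = new_scale_def("rho", "Risk of Harm to Others", "decision_tree",
                        c("violence_extreme_behavior", "violent_ideation",
                          "intimidation_threats", "insight_problem",
                          "delusions", "sleep_disturbance"),
                        mce, 0L, 6L, subscales = c("abs", "pss"),
                        tree = default_rho_tree()),
    sci = new_scale_def("sci", "Self-Care Index", "decision_tree",
                        c("personal_hygiene", "insight_problem",
                          "decreased_energy", "making_self_understood",
                          "anhedonia"),
                        mce, 0L, 6L, subscales = c("cps", "pss", "mania"),
                        tree = default_sci_tree()),
    sss = new_scale_def("sss", "Severity of Self-harm Scale", "decision_tree",
                        c("self_harm_ideation", "suicide_attempts",
                          "suicide_plan", "others_concerned"),
                        mce, 0L, 6L, subscales = c("dsi", "pss", "cps"),
                        tree = default_sss_tree())
  )
  if (extras) {
    defs$sws <- new_scale_def("sws", "Social Withdrawal Scale", "sum",
                              c("avoids_social_contact", "declines_group_activity",
                                "stays_in_room", "no_close_relationships"),
                              mce, 0L, 12L)
  }
  validate_scale_defs(defs)
  defs
}

# Load-time checks: sum ranges consistent with the registry's coding
# ranges, tree leaves in 0..6, and every tree variable declared as a
# component or sub-scale.
validate_scale_defs <- function(defs, registry = mh_registry()) {
  items <- registry$items
  for (def in defs) {
    miss <- setdiff(def$components, items$item_code)
    if (length(miss)) {
      stop("scale '", def$name, "' references unknown item(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (def$kind == "sum") {
      maxes <- items$max_code[match(def$components, items$item_code)]
      if (!is.null(def$component_max)) {
        maxes <- pmin(maxes, def$component_max[def$components])
      }
      if (sum(maxes) != def$out_max) {
        stop(sprintf("scale '%s': component maxima sum to %d, range says %d",
                     def$name, sum(maxes), def$out_max), call. = FALSE)
      }
    } else {
      check_tree(def$tree, def)
    }
  }
  invisible(defs)
}

check_tree <- function(node, def) {
  if (!is.null(node$score)) {
    if (node$score < 0L || node$score > 6L) {
      stop("scale '", def$name, "': tree leaf outside 0-6", call. = FALSE)
    }
    return(invisible(TRUE))
  }
  allowed <- c(def$components, def$subscales)
  if (!node$var %in% allowed) {
    stop("scale '", def$name, "': tree references '", node$var,
         "', which is neither a component nor a declared sub-scale",
         call. = FALSE)
  }
  check_tree(node$yes, def)
  check_tree(node$no, def)
}

# Enumerate every root-to-leaf path of a tree (used by tests as an oracle
# and by documentation helpers).
tree_paths <- function(node, conds = list()) {
  if (!is.null(node$score)) {
    return(list(list(conds = conds, score = node$score)))
  }
  c(
    tree_paths(node$yes, c(conds, list(list(var = node$var, value = node$value, yes = TRUE)))),
    tree_paths(node$no, c(conds, list(list(var = node$var, value = node$value, yes = FALSE))))
  )
}

score_id_cols <- function(records) {
  intersect(record_id_cols(), names(records))
}

get_item_col <- function(records, code, n) {
  if (code %in% names(records)) records[[code]] else rep(NA_integer_, n)
}

check_components_in_instrument <- function(def, records, registry) {
  for (ins in unique(records$instrument)) {
    ins <- match_instrument(ins)
    in_ins <- registry$items$item_code[registry$items[[membership_col(ins)]]]
    miss <- setdiff(def$components, in_ins)
    if (length(miss)) {
      stop(sprintf(
        "scale/instrument mismatch: scale '%s' component(s) %s are not in the %s registry",
        def$name, paste(miss, collapse = ", "), ins), call. = FALSE)
    }
  }
}

#' Score a parallel-form sum scale
#'
#' Sums the component item responses of one sum scale.  By default no
#' imputation is performed: a record with any missing component yields a
#' missing value and `complete = FALSE`.  With `prorate = TRUE`, records
#' with at least one observed component are rescaled by
#' k / (k - n_missing) and rounded half to even.
#'
#' @param records Tibble of assessment records.
#' @param def An `mh_scale_def` with `kind = "sum"`.
#' @param registry An `mh_registry`.
#' @param prorate Prorate partially missing records?
#' @return A tibble: the record id columns plus `scale`, `value`,
#'   `n_missing_components`, `complete`.
#' @export
score_sum_scale <- function(records, def, registry = mh_registry(),
                            prorate = FALSE) {
  stopifnot(inherits(def, "mh_scale_def"), def$kind == "sum")
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  check_components_in_instrument(def, records, registry)
  mat <- vapply(def$components, function(cc) {
    v <- as.numeric(get_item_col(records, cc, n))
    if (!is.null(def$component_max) && cc %in% names(def$component_max)) {
      v <- pmin(v, def$component_max[[cc]])
    }
    v
  }, numeric(n))
  mat <- matrix(mat, nrow = n)
  k <- length(def$components)
  n_missing <- as.integer(rowSums(is.na(mat)))
  value <- ifelse(n_missing == 0L, rowSums(mat), NA_real_)
  if (prorate) {
    partial <- n_missing > 0L & n_missing < k
    if (any(partial)) {
      sums <- rowSums(mat, na.rm = TRUE)
      value[partial] <- round(sums[partial] * k / (k - n_missing[partial]))
    }
  }
  out <- records[, score_id_cols(records), drop = FALSE]
  out$scale <- def$name
  out$value <- as.integer(value)
  out$n_missing_components <- n_missing
  out$complete <- n_missing == 0L
  tibble::as_tibble(out)
}

eval_tree_vec <- function(node, data, n) {
  if (!is.null(node$score)) return(rep(node$score, n))
  v <- data[[node$var]]
  if (is.null(v)) v <- rep(NA_integer_, n)
  test <- v >= node$value
  yes <- eval_tree_vec(node$yes, data, n)
  no <- eval_tree_vec(node$no, data, n)
  out <- rep(NA_integer_, n)
  take_default <- is.na(test) & !is.null(node$default)
  if (any(take_default)) {
    test[take_default] <- identical(node$default, "yes")
  }
  out[which(test)] <- yes[which(test)]
  out[which(!test)] <- no[which(!test)]
  out
}

#' Score a decision-tree scale
#'
#' Evaluates a tree scale's declarative decision tree on each record.
#' Conditions may reference component items or declared sub-scales; any
#' condition on the realized path that touches a missing value yields a
#' missing score (unless that tree node declares a `default` branch).
#'
#' @inheritParams score_sum_scale
#' @param def An `mh_scale_def` with `kind = "decision_tree"`.
#' @param subscale_values Optional tibble/data frame of pre-computed
#'   sub-scale scores, one column per sub-scale name.  When omitted, the
#'   needed sub-scales are computed from the shipped definitions.
#' @return A tibble as for [score_sum_scale()].
#' @export
score_tree_scale <- function(records, def, registry = mh_registry(),
                             subscale_values = NULL) {
  stopifnot(inherits(def, "mh_scale_def"), def$kind == "decision_tree")
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  check_components_in_instrument(def, records, registry)
  data <- records
  if (length(def$subscales)) {
    if (is.null(subscale_values)) {
      all_defs <- scale_definitions()
      subscale_values <- compute_subscales(records, def$subscales, all_defs, registry)
    }
    for (s in def$subscales) data[[s]] <- subscale_values[[s]]
  }
  value <- eval_tree_vec(def$tree, data, n)
  comp_mat <- vapply(def$components, function(cc) {
    is.na(get_item_col(records, cc, n))
  }, logical(n))
  comp_mat <- matrix(comp_mat, nrow = n)
  out <- records[, score_id_cols(records), drop = FALSE]
  out$scale <- def$name
  out$value <- as.integer(value)
  out$n_missing_components <- as.integer(rowSums(comp_mat))
  out$complete <- !is.na(value)
  tibble::as_tibble(out)
}

compute_subscales <- function(records, needed, all_defs, registry) {
  out <- list()
  for (s in needed) {
    d <- all_defs[[s]]
    if (is.null(d)) stop("undeclared sub-scale: ", s, call. = FALSE)
    sc <- if (d$kind == "sum") {
      score_sum_scale(records, d, registry)
    } else {
      score_tree_scale(records, d, registry)
    }
    out[[s]] <- sc$value
  }
  tibble::as_tibble(out)
}

#' Score all applicable scales
#'
#' Scores every definition applicable to each record's instrument and
#' returns one long tibble.  Inapplicable scales are omitted for that
#' record, never scored as zero: a BMHS record yields only the Positive
#' Symptoms Scale, an ESP record the nine ESP scales, an MH or CMH record
#' all thirteen.
#'
#' @inheritParams score_sum_scale
#' @param defs Named list of `mh_scale_def` (default [scale_definitions()]).
#' @return Long tibble: id columns plus `scale`, `value`,
#'   `n_missing_components`, `complete`.
#' @export
#' @examples
#' reg <- build_registry()
#' rec <- tibble::tibble(person_id = "p1", instrument = "BMHS",
#'                       reason = "screen", date = as.Date("2020-06-01"),
#'                       hallucinations = 3L, command_hallucinations = 3L,
#'                       delusions = 3L, abnormal_thought_process = 3L)
#' score_scales(rec, reg)
score_scales <- function(records, registry = mh_registry(),
                         defs = scale_definitions(), prorate = FALSE) {
  records <- tibble::as_tibble(records)
  pieces <- list()
  for (ins in unique(records$instrument)) {
    ins_ok <- match_instrument(ins)
    sub <- records[records$instrument == ins, , drop = FALSE]
    applicable <- Filter(function(d) ins_ok %in% d$instruments, defs)
    # sum scales first, then trees in dependency order
    ordered <- c(
      Filter(function(d) d$kind == "sum", applicable),
      tree_dependency_order(Filter(function(d) d$kind == "decision_tree", applicable))
    )
    sub_values <- list()
    for (d in ordered) {
      sc <- if (d$kind == "sum") {
        score_sum_scale(sub, d, registry, prorate = prorate)
      } else {
        need <- d$subscales
        missing_sub <- setdiff(need, names(sub_values))
        if (length(missing_sub)) {
          extra <- compute_subscales(sub, missing_sub, defs, registry)
          for (s in missing_sub) sub_values[[s]] <- extra[[s]]
        }
        score_tree_scale(sub, d, registry,
                         subscale_values = tibble::as_tibble(sub_values[need]))
      }
      sub_values[[d$name]] <- sc$value
      pieces[[paste(ins, d$name)]] <- sc
    }
  }
  if (!length(pieces)) {
    return(tibble::tibble(person_id = character(), scale = character(),
                          value = integer(), n_missing_components = integer(),
                          complete = logical()))
  }
  dplyr::bind_rows(pieces)
}

tree_dependency_order <- function(tree_defs) {
  if (!length(tree_defs)) return(list())
  names_left <- names(tree_defs)
  ordered <- list()
  done <- character()
  while (length(names_left)) {
    progressed <- FALSE
    for (nm in names_left) {
      deps <- intersect(tree_defs[[nm]]$subscales, names(tree_defs))
      if (all(deps %in% done)) {
        ordered[[nm]] <- tree_defs[[nm]]
        done <- c(done, nm)
        names_left <- setdiff(names_left, nm)
        progressed <- TRUE
      }
    }
    if (!progressed) stop("cyclic sub-scale dependencies", call. = FALSE)
  }
  ordered
}
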