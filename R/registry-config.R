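# Default item registry configuration.
#
# The instrument item counts (MH 396, CMH 405, ESP 141, BMHS 46; 330 items
# shared by MH and CMH) and the per-domain allocations are structural facts
# of the published instrument family.  The items themselves are proprietary,
# so this registry ships a synthetic item namespace: clinically named items
# back every summary scale and trigger rule, and anonymous filler items
# complete each domain's printed count.  Published per-domain counts do not
# sum to the instrument totals; the remainder is carried in an
# "unclassified" domain so that every printed total and overlap is exact.

mh_domains <- function() {
  c(
    "administrative & tracking", "mental status indicators",
    "substance use/addictions", "harm to self/others", "behavior",
    "cognition", "functional status", "communication & vision",
    "physical health conditions", "stress & trauma", "medications",
    "service use & treatments", "control interventions",
    "nutritional status", "social relations",
    "employment, education & finances",
    "housing, home environment, living arrangements", "diagnoses",
    "unclassified"
  )
}

# Printed per-domain item counts for the four adult instruments.
domain_count_table <- function() {
  tibble::tribble(
    ~domain,                                            ~prefix, ~mh, ~cmh, ~esp, ~bmhs,
    "administrative & tracking",                        "adm",    43,   39,   27,    22,
    "mental status indicators",                         "msi",    42,   40,   33,     8,
    "substance use/addictions",                         "sub",    17,   19,   10,     1,
    "harm to self/others",                              "hrm",    13,   17,   12,     9,
    "behavior",                                         "beh",     9,    6,    5,     2,
    "cognition",                                        "cog",     8,    8,    5,     1,
    "functional status",                                "fun",    16,   23,    3,     0,
    "communication & vision",                           "com",     4,    4,    1,     0,
    "physical health conditions",                       "phy",    40,   41,    0,     0,
    "stress & trauma",                                  "str",    19,   21,    1,     0,
    "medications",                                      "med",     5,    4,    4,     1,
    "service use & treatments",                         "svc",    36,   36,    2,     0,
    "control interventions",                            "ctl",    13,    0,    0,     0,
    "nutritional status",                               "nut",    10,   10,    0,     0,
    "social relations",                                 "soc",    12,   31,    9,     0,
    "employment, education & finances",                 "emp",     9,    9,    0,     0,
    "housing, home environment, living arrangements",   "hou",     5,   10,    6,     3,
    "diagnoses",                                        "dxg",    30,   28,   16,     0
  )
}

default_lookback_for <- function(domain) {
  dplyr::case_when(
    domain == "service use & treatments" ~ "7-day",
    domain == "medications" ~ "7-day",
    domain == "diagnoses" ~ "lifetime",
    domain == "housing, home environment, living arrangements" ~ "30-day",
    domain == "employment, education & finances" ~ "90-day",
    TRUE ~ "3-day"
  )
}

# Clinically named items: the components of every shipped scale, decision
# tree and CAP trigger rule.  membership: "core" = in both MH and CMH.
# esp/bmhs flags mark membership in the subset instruments.
named_item_table <- function() {
  t <- tibble::tribble(
    ~item_code,                    ~label,                                        ~domain_prefix, ~max_code, ~esp, ~bmhs,
    # Positive Symptoms Scale (also on BMHS)
    "hallucinations",              "Hallucinations",                              "msi", 3L, TRUE,  TRUE,
    "command_hallucinations",      "Command hallucinations",                      "msi", 3L, TRUE,  TRUE,
    "delusions",                   "Delusions",                                   "msi", 3L, TRUE,  TRUE,
    "abnormal_thought_process",    "Abnormal thought process",                    "msi", 3L, TRUE,  TRUE,
    # Depressive Severity Index
    "sad_facial_expression",       "Sad, pained facial expressions",              "msi", 3L, TRUE,  FALSE,
    "negative_statements",         "Negative statements",                         "msi", 3L, TRUE,  FALSE,
    "self_deprecation",            "Self-deprecation",                            "msi", 3L, TRUE,  FALSE,
    "guilt_shame",                 "Expressions of guilt or shame",               "msi", 3L, TRUE,  FALSE,
    "hopelessness",                "Hopelessness",                                "msi", 3L, TRUE,  FALSE,
    # Negative Symptoms Scale
    "anhedonia",                   "Anhedonia",                                   "msi", 3L, TRUE,  FALSE,
    "withdrawal_from_activities",  "Withdrawal from activities of interest",      "msi", 3L, TRUE,  FALSE,
    "lack_of_motivation",          "Lack of motivation",                          "msi", 3L, TRUE,  FALSE,
    "reduced_social_interactions", "Reduced social interactions",                 "msi", 3L, TRUE,  FALSE,
    # Mania scale (sleep problems item coded 0-2 so the scale tops at 20)
    "inflated_self_worth",         "Inflated self-worth",                         "msi", 3L, TRUE,  FALSE,
    "hyperarousal",                "Hyperarousal",                                "msi", 3L, TRUE,  FALSE,
    "irritability",                "Irritability",                                "msi", 3L, TRUE,  FALSE,
    "increased_sociability",       "Increased sociability/hypersexuality",        "msi", 3L, TRUE,  FALSE,
    "pressured_speech",            "Pressured speech",                            "msi", 3L, TRUE,  FALSE,
    "labile_affect",               "Labile affect",                               "msi", 3L, TRUE,  FALSE,
    "sleep_problems_hypomania",    "Sleep problems - hypomania",                  "msi", 2L, TRUE,  FALSE,
    # Social Withdrawal Scale (synthetic component set; bands 0/1-4/5-8/9-12)
    "avoids_social_contact",       "Avoids social contact",                       "msi", 3L, TRUE,  FALSE,
    "declines_group_activity",     "Declines group activities",                   "msi", 3L, TRUE,  FALSE,
    "stays_in_room",               "Stays in room / does not go out",             "msi", 3L, TRUE,  FALSE,
    "no_close_relationships",      "No close relationships",                      "msi", 3L, TRUE,  FALSE,
    # Decision-tree and CAP inputs
    "insight_problem",             "Insight into mental health condition (0 full, 2 none)", "msi", 2L, TRUE, FALSE,
    "decreased_energy",            "Decreased energy",                            "msi", 3L, TRUE,  FALSE,
    "sleep_disturbance",           "Sleep disturbance",                           "msi", 3L, TRUE,  FALSE,
    # Harm to self/others
    "self_harm_ideation",          "Self-harm ideation",                          "hrm", 3L, TRUE,  FALSE,
    "suicide_attempts",            "Suicide attempts",                            "hrm", 3L, TRUE,  FALSE,
    "suicide_plan",                "Suicide plan",                                "hrm", 1L, TRUE,  FALSE,
    "others_concerned",            "Others concerned about risk of self-harm",    "hrm", 1L, TRUE,  FALSE,
    "violence_extreme_behavior",   "Violence / extreme behavior",                 "hrm", 3L, TRUE,  FALSE,
    "violent_ideation",            "Violent ideation",                            "hrm", 3L, TRUE,  FALSE,
    "intimidation_threats",        "Intimidation of others / threats",            "hrm", 3L, TRUE,  FALSE,
    # Aggressive Behavior Scale
    "verbal_abuse",                "Verbal abuse",                                "beh", 3L, TRUE,  TRUE,
    "physical_abuse",              "Physical abuse",                              "beh", 3L, TRUE,  TRUE,
    "socially_inappropriate",      "Socially inappropriate/disruptive behavior",  "beh", 3L, TRUE,  FALSE,
    "resists_care",                "Resists care",                                "beh", 3L, TRUE,  FALSE,
    # Cognition
    "daily_decision_making",       "Daily decision making",                       "cog", 3L, TRUE,  TRUE,
    "short_term_memory",           "Short-term memory problem",                   "cog", 1L, TRUE,  FALSE,
    # Communication
    "making_self_understood",      "Making self understood (expression)",         "com", 3L, TRUE,  FALSE,
    # ADL (0-4 performance coding)
    "adl_eating",                  "Eating",                                      "fun", 4L, TRUE,  FALSE,
    "personal_hygiene",            "Personal hygiene",                            "fun", 4L, TRUE,  FALSE,
    "locomotion",                  "Locomotion",                                  "fun", 4L, TRUE,  FALSE,
    "toilet_use",                  "Toilet use",                                  "fun", 4L, FALSE, FALSE,
    # IADL capacity (meal preparation 0-6 so the scale tops at 30)
    "meal_preparation",            "Meal preparation",                            "fun", 6L, FALSE, FALSE,
    "ordinary_housework",          "Ordinary housework",                          "fun", 4L, FALSE, FALSE,
    "managing_finances",           "Managing finances",                           "fun", 4L, FALSE, FALSE,
    "managing_medications",        "Managing medications",                        "fun", 4L, FALSE, FALSE,
    "phone_use",                   "Phone use",                                   "fun", 4L, FALSE, FALSE,
    "shopping",                    "Shopping",                                    "fun", 4L, FALSE, FALSE,
    "transportation",              "Transportation",                              "fun", 4L, FALSE, FALSE,
    # Substance use / addictions
    "withdrawal_symptoms",         "Substance withdrawal symptoms",               "sub", 2L, TRUE,  FALSE,
    "smokes_daily",                "Smokes tobacco daily",                        "sub", 1L, TRUE,  TRUE,
    "count_substances",            "Count of current substances used",            "sub", 5L, TRUE,  FALSE,
    "misuse_prescription_meds",    "Misuse of prescription medications",          "sub", 1L, TRUE,  FALSE,
    "days_drank_intox",            "Days drank to intoxication (0, 1-8, 9-daily)","sub", 2L, TRUE,  FALSE,
    "five_plus_drinks",            "5+ drinks in a single sitting",               "sub", 1L, TRUE,  FALSE,
    "cage_cut_down",               "Felt need to cut down substance use",         "sub", 1L, FALSE, FALSE,
    "cage_angered",                "Angered by criticisms of use",                "sub", 1L, FALSE, FALSE,
    "cage_guilt",                  "Guilt about substance use",                   "sub", 1L, FALSE, FALSE,
    "cage_morning",                "Drinking/using in the morning",               "sub", 1L, FALSE, FALSE,
    # Pain (two items, each 0-2, scale 0-4)
    "pain_frequency",              "Pain frequency",                              "phy", 2L, FALSE, FALSE,
    "pain_intensity",              "Pain intensity",                              "phy", 2L, FALSE, FALSE,
    "falls",                       "Falls",                                       "phy", 2L, FALSE, FALSE,
    "low_physical_activity",       "Low physical activity",                       "phy", 2L, FALSE, FALSE,
    # Stress & trauma
    "recent_trauma",               "Assault/abuse/victimization in last 7 days",  "str", 1L, TRUE,  FALSE,
    "traumatic_event_fear",        "Traumatic life event with intense fear",      "str", 3L, FALSE, FALSE,
    # Medications
    "stopped_meds",                "Stopped psychiatric medications",             "med", 1L, TRUE,  TRUE,
    "med_adherence_problem",       "Medication adherence problem",                "med", 2L, TRUE,  FALSE,
    # Service use
    "prior_hospitalizations",      "Prior psychiatric admissions",                "svc", 3L, TRUE,  FALSE,
    "control_intervention_history","History of control interventions",            "svc", 2L, TRUE,  FALSE,
    # Social relations
    "conflict_with_others",        "Conflict with family/friends",                "soc", 2L, TRUE,  FALSE,
    "informal_support_problem",    "Informal support insufficient",               "soc", 2L, TRUE,  FALSE,
    "lack_of_discharge_support",   "No support arrangement for discharge",        "soc", 1L, TRUE,  FALSE,
    # Employment, education & finances
    "education_employment_risk",   "Risk of education/employment disruption",     "emp", 2L, FALSE, FALSE,
    "economic_hardship",           "Economic hardship",                           "emp", 2L, FALSE, FALSE,
    # Nutrition
    "bmi_problem",                 "Problem body-mass index",                     "nut", 1L, FALSE, FALSE,
    "eating_behavior",             "Problematic eating behavior",                 "nut", 2L, FALSE, FALSE
  )
  dc <- domain_count_table()
  t$domain <- dc$domain[match(t$domain_prefix, dc$prefix)]
  t$min_code <- 0L
  t$membership <- "core"
  t
}

#' Default registry configuration
#'
#' Builds the shipped registry configuration: a table of item definitions
#' with instrument membership for the adult mental-health instruments
#' (MH, CMH, ESP, BMHS) plus placeholder forensic (FS) and addiction (AS)
#' supplements, and the expected instrument cardinalities that
#' [build_registry()] verifies.
#'
#' The per-domain allocation reproduces the printed counts for every
#' domain of the MH and CMH; subset instruments take the largest
#' realizable per-domain allocation compatible with the subset structure
#' (BMHS items are a subset of ESP items, which are a subset of the items
#' the MH and CMH share); the balance of each instrument's printed total
#' is carried by "unclassified" items.
#'
#' @return A list with elements `items` (a tibble of item definitions:
#'   `item_code`, `label`, `domain`, `min_code`, `max_code`, `lookback`,
#'   and logical membership columns `in_mh`, `in_cmh`, `in_esp`,
#'   `in_bmhs`, `in_fs`, `in_as`), `instruments` (per-instrument default
#'   look-back periods), and `expected` (cardinality invariants).
#' @seealso [build_registry()]
#' @export
#' @examples
#' cfg <- default_registry_config()
#' sum(cfg$items$in_mh)   # 396
default_registry_config <- function() {
  dc <- domain_count_table()
  named <- named_item_table()

  # Per-domain quotas.  Core = shared MH/CMH pool; subset instruments draw
  # from it.  ESP quota capped by the core quota (the housing overflow and
  # the remainder to 141 live in the unclassified pool); the BMHS total is
  # capped at 46 by trimming the administrative allocation.
  dc$core <- pmin(dc$mh, dc$cmh)
  dc$esp_q <- pmin(dc$esp, dc$core)
  dc$bmhs_q <- pmin(dc$bmhs, dc$esp_q)
  over <- sum(dc$bmhs_q) - 46L
  if (over > 0L) {
    i <- which.max(dc$bmhs_q)
    dc$bmhs_q[i] <- dc$bmhs_q[i] - over
  }

  rows <- vector("list", nrow(dc))
  for (i in seq_len(nrow(dc))) {
    d <- dc[i, ]
    nm <- named[named$domain == d$domain, ]
    stopifnot(
      nrow(nm) <= d$core, sum(nm$esp) <= d$esp_q, sum(nm$bmhs) <= d$bmhs_q
    )
    n_gen_core <- d$core - nrow(nm)
    n_gen_mh <- d$mh - d$core
    n_gen_cmh <- d$cmh - d$core
    gen_n <- n_gen_core + n_gen_mh + n_gen_cmh
    gen_max <- if (d$domain %in% c("administrative & tracking", "diagnoses")) 1L else 3L
    gen <- tibble::tibble(
      item_code = sprintf("%s_%03d", d$prefix, seq_len(gen_n)),
      label = sprintf("%s item %d", d$domain, seq_len(gen_n)),
      domain = d$domain,
      min_code = 0L,
      max_code = gen_max,
      membership = rep(c("core", "mh", "cmh"), c(n_gen_core, n_gen_mh, n_gen_cmh)),
      esp = FALSE, bmhs = FALSE
    )
    # Fill subset-instrument quotas from core items: named flags first,
    # then generic core items in order.
    need_esp <- d$esp_q - sum(nm$esp)
    idx <- which(gen$membership == "core")
    gen$esp[idx[seq_len(need_esp)]] <- TRUE
    block <- dplyr::bind_rows(
      nm[, c("item_code", "label", "domain", "min_code", "max_code",
             "membership", "esp", "bmhs")],
      gen
    )
    need_bmhs <- d$bmhs_q - sum(block$bmhs)
    if (need_bmhs > 0L) {
      cand <- which(block$esp & !block$bmhs)
      block$bmhs[cand[seq_len(need_bmhs)]] <- TRUE
    }
    rows[[i]] <- block
  }
  items <- dplyr::bind_rows(rows)

  # Unclassified padding to the printed instrument totals.
  n_unc_core <- 330L - sum(items$membership == "core")
  n_unc_mh <- 396L - 330L - sum(items$membership == "mh")
  n_unc_cmh <- 405L - 330L - sum(items$membership == "cmh")
  n_unc_esp <- 141L - sum(items$esp)
  unc <- tibble::tibble(
    item_code = sprintf("unc_%03d", seq_len(n_unc_core + n_unc_mh + n_unc_cmh)),
    label = sprintf("unclassified item %d", seq_len(n_unc_core + n_unc_mh + n_unc_cmh)),
    domain = "unclassified",
    min_code = 0L, max_code = 3L,
    membership = rep(c("core", "mh", "cmh"), c(n_unc_core, n_unc_mh, n_unc_cmh)),
    esp = FALSE, bmhs = FALSE
  )
  unc$esp[which(unc$membership == "core")[seq_len(n_unc_esp)]] <- TRUE
  items <- dplyr::bind_rows(items, unc)

  supp <- tibble::tibble(
    item_code = c(sprintf("fsx_%03d", 1:33), sprintf("asx_%03d", 1:35)),
    label = c(sprintf("forensic supplement item %d", 1:33),
              sprintf("addiction supplement item %d", 1:35)),
    domain = "unclassified",
    min_code = 0L, max_code = 3L,
    membership = rep(c("fs", "as"), c(33L, 35L)),
    esp = FALSE, bmhs = FALSE
  )
  items <- dplyr::bind_rows(items, supp)

  items <- tibble::tibble(
    item_code = items$item_code,
    label = items$label,
    domain = items$domain,
    min_code = items$min_code,
    max_code = as.integer(items$max_code),
    lookback = default_lookback_for(items$domain),
    in_mh = items$membership %in% c("core", "mh"),
    in_cmh = items$membership %in% c("core", "cmh"),
    in_esp = items$esp,
    in_bmhs = items$bmhs,
    in_fs = items$membership == "fs",
    in_as = items$membership == "as"
  )

  list(
    items = items,
    instruments = tibble::tibble(
      code = c("MH", "CMH", "ESP", "BMHS", "FS", "AS"),
      default_lookback = c("3-day", "3-day", "24-hour", "24-hour", "3-day", "3-day")
    ),
    expected = list(
      MH = 396L, CMH = 405L, ESP = 141L, BMHS = 46L, FS = 33L, AS = 35L,
      mh_cmh_shared = 330L, cmh_only = 75L, mh_only = 66L
    )
  )
}
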