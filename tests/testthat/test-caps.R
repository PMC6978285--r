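test_that("the protocol applicability matrix matches the published table", {
  defs <- cap_definitions()
  expect_equal(nrow(defs), 21)
  expect_equal(sum(defs$mh), 20)
  expect_equal(sum(defs$cmh), 20)
  expect_equal(sum(defs$esp), 4)
  # the inpatient and community instruments differ only on the two
  # support protocols
  diff <- defs$cap[defs$mh != defs$cmh]
  expect_setequal(diff, c("informal_support", "support_systems_discharge"))
  # emergency screener: the three safety protocols plus smoking
  expect_setequal(defs$cap[defs$esp],
                  c("harm_to_others", "suicidality_self_harm", "self_care",
                    "smoking"))
  expect_true(all(defs$n_levels[defs$group == "safety"] == 2L))
  expect_equal(defs$n_levels[defs$cap == "support_systems_discharge"], 1L)
  expect_equal(defs$n_levels[defs$cap == "criminal_activity"], 1L)
})

test_that("an ESP record yields exactly four protocol results", {
  reg <- test_registry()
  esp <- full_record("ESP", 1L)
  res <- evaluate_caps(esp, reg)
  expect_equal(nrow(res), 4)
  expect_true(all(res$level <= res$n_levels))
})

test_that("an all-zero record triggers nothing", {
  reg <- test_registry()
  res <- evaluate_caps(full_record("MH", 0L), reg)
  expect_equal(nrow(res), 20)
  expect_true(all(res$level == 0L))
  expect_true(all(res$inputs_complete))
})

test_that("trigger levels equal direct re-evaluation of each rule predicate", {
  reg <- test_registry()
  recs <- random_records(300, "MH", p_missing = 0.05, seed = 23)
  defs <- cap_definitions()
  scores <- mhassess:::scores_to_wide(
    score_scales(recs, reg, defs = scale_definitions(extras = TRUE)), recs)
  got <- evaluate_caps(recs, reg, defs, scores = scores)
  for (j in seq_len(nrow(defs))) {
    if (!defs$mh[j]) next
    rules <- defs$rules[[j]]
    for (i in seq_len(nrow(recs))) {
      lev <- 0L
      for (k in seq_along(rules)) {         # highest level listed first
        this <- length(rules) - k + 1L
        holds <- TRUE
        for (cond in rules[[k]]) {
          v <- if (cond$var %in% names(scores)) scores[[cond$var]][i]
               else recs[[cond$var]][i]
          if (is.na(v) || v < cond$value) holds <- FALSE
        }
        if (holds) { lev <- this; break }
      }
      g <- got$level[got$cap == defs$cap[j] &
                     got$person_id == recs$person_id[i]]
      expect_identical(g, lev)
    }
  }
})

test_that("raising a rule input never lowers the triggered level", {
  reg <- test_registry()
  recs <- random_records(150, "MH", seed = 29)
  base <- evaluate_caps(recs, reg)
  # push every safety-scale input to its maximum
  worst <- recs
  for (cc in c("violence_extreme_behavior", "suicide_attempts", "suicide_plan",
               "personal_hygiene", "daily_decision_making")) {
    worst[[cc]] <- registry_items(reg)$max_code[
      registry_items(reg)$item_code == cc]
  }
  after <- evaluate_caps(worst, reg)
  for (cap in c("harm_to_others", "suicidality_self_harm", "self_care")) {
    b <- base$level[base$cap == cap]
    a <- after$level[after$cap == cap]
    expect_true(all(a >= b), label = cap)
  }
})

test_that("a rule referencing a scale unavailable on its instrument is a config error", {
  reg <- test_registry()
  defs <- cap_definitions()
  bad <- defs[defs$cap == "pain", ]
  bad$esp <- TRUE   # PAIN scale is not collected on the ESP
  expect_error(evaluate_caps(full_record("ESP", 0L), reg, defs = bad),
               "unavailable on ESP")
})

test_that("triggering rates are stratified counts over stratum sizes", {
  res <- tibble::tibble(
    person_id = sprintf("p%02d", 1:10), cap = "self_care", group = "safety",
    level = c(1L, 1L, 1L, rep(0L, 7)), n_levels = 2L,
    inputs_complete = TRUE, homeless = rep(TRUE, 10))
  tr <- triggering_rates(res, "homeless")
  any_row <- tr[is.na(tr$level), ]
  expect_equal(any_row$n_triggered, 3L)
  expect_equal(any_row$n, 10L)
  expect_equal(any_row$rate, 0.3)

  all_l2 <- dplyr::mutate(res, level = 2L)
  tr2 <- triggering_rates(all_l2, "homeless")
  expect_true(all(tr2$rate[which(tr2$level == 2L)] == 1))

  expect_error(triggering_rates(res, "nope"), "unknown stratifier")
})

test_that("a homeless latent-severity shift raises safety-protocol rates", {
  cohort <- simulate_cohort(sim_config(n = 4000), seed = 31)
  res <- evaluate_caps(cohort)
  res <- dplyr::left_join(res,
                          dplyr::select(cohort, "person_id", "homeless"),
                          by = "person_id")
  tr <- triggering_rates(res, "homeless")
  for (cap in c("harm_to_others", "suicidality_self_harm", "self_care")) {
    r <- tr[is.na(tr$level) & tr$cap == cap, ]
    expect_gt(r$rate[r$stratum], r$rate[!r$stratum], label = cap)
  }
})
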