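make_records <- function(rows) {
  # rows: list of c(pid, reason, day, pss-ish severity 0..3 on each item)
  recs <- lapply(rows, function(r) {
    tibble::tibble(
      person_id = r$pid, instrument = "MH", reason = r$reason,
      date = as.Date("2020-01-01") + r$day,
      hallucinations = r$sev, command_hallucinations = r$sev,
      delusions = r$sev, abnormal_thought_process = r$sev)
  })
  dplyr::bind_rows(recs)
}

test_that("pairing follows the 90-day-or-discharge rule", {
  # admission day 0 + discharge day 30 -> uses day 30
  recs <- make_records(list(
    list(pid = "a", reason = "admission", day = 0, sev = 2L),
    list(pid = "a", reason = "discharge", day = 30, sev = 1L)))
  p <- pair_followups(recs, "pss")
  expect_equal(nrow(p), 1)
  expect_equal(p$followup_date, as.Date("2020-01-31"))
  expect_equal(p$baseline, 8L)
  expect_equal(p$followup, 4L)

  # admission day 0, review day 90, discharge day 120 -> uses the review
  recs <- make_records(list(
    list(pid = "b", reason = "admission", day = 0, sev = 3L),
    list(pid = "b", reason = "review", day = 90, sev = 2L),
    list(pid = "b", reason = "discharge", day = 120, sev = 0L)))
  p <- pair_followups(recs, "pss")
  expect_equal(p$followup_reason, "review")
  expect_equal(as.integer(p$followup_date - p$baseline_date), 90L)

  # discharge beyond 90 days and no review -> excluded, counted in the log
  recs <- make_records(list(
    list(pid = "c", reason = "admission", day = 0, sev = 2L),
    list(pid = "c", reason = "discharge", day = 120, sev = 0L)))
  p <- pair_followups(recs, "pss")
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "excluded")$why, "no_followup_in_window")
})

test_that("non-monotone episodes are skipped with a log entry", {
  recs <- make_records(list(
    list(pid = "e", reason = "admission", day = 50, sev = 2L),
    list(pid = "e", reason = "discharge", day = 10, sev = 0L)))
  p <- pair_followups(recs, "pss")
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "excluded")$why, "non_monotone_dates")
})

test_that("episodes are bounded by the next admission", {
  recs <- make_records(list(
    list(pid = "d", reason = "admission", day = 0, sev = 3L),
    list(pid = "d", reason = "discharge", day = 20, sev = 1L),
    list(pid = "d", reason = "admission", day = 40, sev = 2L),
    list(pid = "d", reason = "discharge", day = 60, sev = 2L)))
  p <- pair_followups(recs, "pss")
  expect_equal(nrow(p), 2)
  expect_equal(as.integer(p$followup_date - p$baseline_date), c(20L, 20L))
})

test_that("pair counts equal a brute-force episode walk on a simulated cohort", {
  eps <- simulate_episodes(sim_config(n = 200), seed = 41)
  p <- pair_followups(eps, "pss")
  # oracle: persons with an admission and a later follow-up within 90 days
  expected <- 0L
  for (pid in unique(eps$person_id)) {
    sub <- eps[eps$person_id == pid, ]
    adm <- sub[sub$reason == "admission", ]
    fu <- sub[sub$reason %in% c("review", "discharge"), ]
    if (nrow(adm) == 1 && nrow(fu) >= 1 &&
        min(as.integer(fu$date - adm$date)) <= 90) {
      expected <- expected + 1L
    }
  }
  expect_equal(nrow(p), expected)
  expect_equal(nrow(p) + nrow(attr(p, "excluded")),
               sum(eps$reason == "admission"))
})

test_that("the two outcome definitions match their stated denominators and events", {
  pairs <- tibble::tibble(
    person_id = letters[1:4], scale = "dsi",
    baseline = c(3L, 0L, 2L, 5L), followup = c(1L, 0L, 2L, 4L))
  imp <- compute_qi(pairs, "improvement")
  expect_equal(imp$numerator, 2L)
  expect_equal(imp$denominator, 3L)
  expect_equal(imp$rate, 2 / 3)
  fail <- compute_qi(pairs, "failure")
  expect_equal(fail$numerator, 2L)   # 0->0 and 2->2
  expect_equal(fail$denominator, 4L)
  expect_equal(fail$rate, 1 / 2)
  # strict-worsening variant: no strict worsenings here
  strict <- compute_qi(pairs, "failure", strict_worsening = TRUE)
  expect_equal(strict$numerator, 0L)

  same <- dplyr::mutate(pairs, followup = baseline)
  expect_equal(compute_qi(same, "improvement")$rate, 0)
  expect_equal(compute_qi(same, "failure")$rate, 1)
})

test_that("improvement and failure partition non-boundary pairs", {
  withr::with_seed(43, {
    pairs <- tibble::tibble(
      person_id = sprintf("p%03d", 1:500), scale = "pss",
      baseline = sample(0:12, 500, replace = TRUE),
      followup = sample(0:12, 500, replace = TRUE))
    ee_i <- mhassess:::qi_eligible_event(pairs, "improvement")
    ee_f <- mhassess:::qi_eligible_event(pairs, "failure")
    both <- ee_i$event & ee_f$event
    expect_false(any(both))
    interior <- pairs$baseline > 0 & pairs$baseline < 12
    expect_true(all((ee_i$event | ee_f$event)[interior]))
    # oracle check of the counts
    o <- oracle_qi(pairs$baseline, pairs$followup, 12, "improvement")
    expect_equal(sum(ee_i$event), unname(o["num"]))
    expect_equal(sum(ee_i$eligible), unname(o["den"]))
  })
})

test_that("risk adjustment reduces to the observed rate for intercept-only models", {
  withr::with_seed(47, {
    pairs <- tibble::tibble(
      person_id = sprintf("p%03d", 1:300), scale = "pss",
      baseline = sample(1:12, 300, replace = TRUE),
      followup = sample(0:12, 300, replace = TRUE),
      site = sample(c("A", "B"), 300, replace = TRUE))
    adj <- risk_adjust(pairs, "improvement", by = "site",
                       covariates = character())
    expect_equal(adj$adjusted_rate, adj$observed_rate, tolerance = 1e-12)
    # indirect standardization arithmetic: observed/expected x pooled
    expect_equal(adj$expected_rate,
                 rep(sum(adj$numerator) / sum(adj$denominator), 2),
                 tolerance = 1e-12)
  })
})

test_that("rates are invariant to person order and irrelevant covariates", {
  withr::with_seed(53, {
    pairs <- tibble::tibble(
      person_id = sprintf("p%03d", 1:200), scale = "dsi",
      baseline = sample(0:15, 200, replace = TRUE),
      followup = sample(0:15, 200, replace = TRUE),
      shoe_size = sample(35:47, 200, replace = TRUE))
    a <- compute_qi(pairs, "improvement")
    b <- compute_qi(pairs[sample(200), ], "improvement")
    expect_equal(a, b)
  })
})

test_that("trend tables are deterministic and shaped by period and stratum", {
  pairs <- tibble::tibble(
    person_id = sprintf("p%03d", 1:100), scale = "pss",
    baseline = rep(c(2L, 5L), 50), followup = rep(c(1L, 5L), 50),
    period = rep(c(2016L, 2017L), each = 50),
    homeless = rep(c(TRUE, FALSE), 50))
  tr <- qi_trend(pairs, "improvement", by = c("period", "homeless"),
                 covariates = character())
  expect_equal(nrow(tr), 4)
  # identical cohorts in both periods -> identical rates
  expect_equal(tr$adjusted_rate[tr$period == 2016],
               tr$adjusted_rate[tr$period == 2017])
})
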