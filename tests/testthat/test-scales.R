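test_that("sum scales hit zero and the printed maximum at the coding extremes", {
  reg <- test_registry()
  defs <- scale_definitions()
  printed_max <- c(abs = 12, adl = 16, negsym = 12, cage = 4, dsi = 15,
                   iadl = 30, mania = 20, pain = 4, pss = 12)
  zero <- full_record("MH", 0L)
  worst <- full_record("MH", 99L)   # capped at each item's max
  for (s in names(printed_max)) {
    expect_equal(score_sum_scale(zero, defs[[s]], reg)$value, 0L, label = s)
    expect_equal(score_sum_scale(worst, defs[[s]], reg)$value,
                 as.integer(printed_max[[s]]), label = s)
    expect_equal(defs[[s]]$out_max, as.integer(printed_max[[s]]), label = s)
  }
  # the 0-8 variant of the aggression scale caps components at 2
  v8 <- scale_definitions(abs_variant = "0-8")$abs
  expect_equal(v8$out_max, 8L)
  expect_equal(score_sum_scale(worst, v8, reg)$value, 8L)
})

test_that("tree scales span 0 to 6 and hit the extremes at the coding extremes", {
  reg <- test_registry()
  defs <- scale_definitions()
  zero <- full_record("MH", 0L)
  worst <- full_record("MH", 99L)
  for (s in c("cps", "rho", "sci", "sss")) {
    expect_equal(score_tree_scale(zero, defs[[s]], reg)$value, 0L, label = s)
    expect_equal(score_tree_scale(worst, defs[[s]], reg)$value, 6L, label = s)
    leaves <- vapply(mhassess:::tree_paths(defs[[s]]$tree), `[[`, 0L, "score")
    expect_setequal(sort(unique(leaves)), 0:6)
  }
})

test_that("sum scoring equals a naive per-record summation oracle", {
  reg <- test_registry()
  defs <- scale_definitions()
  recs <- random_records(400, "MH", p_missing = 0.1, seed = 11)
  for (s in c("pss", "dsi", "mania", "iadl", "cage")) {
    got <- score_sum_scale(recs, defs[[s]], reg)
    expect_identical(got$value, oracle_sum_scale(recs, defs[[s]]), label = s)
    expect_identical(got$complete, !is.na(got$value))
  }
})

test_that("tree scoring equals scalar path-walking on random records", {
  reg <- test_registry()
  defs <- scale_definitions()
  recs <- random_records(350, "MH", p_missing = 0.05, seed = 13)
  sub_defs <- list()
  for (s in c("cps", "rho", "sci", "sss")) {
    def <- defs[[s]]
    got <- score_tree_scale(recs, def, reg)
    subs <- mhassess:::compute_subscales(recs, def$subscales, defs, reg)
    expected <- vapply(seq_len(nrow(recs)), function(i) {
      values <- as.list(recs[i, def$components])
      for (b in def$subscales) values[[b]] <- subs[[b]][i]
      v <- oracle_tree_scalar(def$tree, values)
      if (is.null(v)) NA_integer_ else as.integer(v)
    }, integer(1))
    expect_identical(got$value, expected, label = s)
    # determinism
    expect_identical(got$value, score_tree_scale(recs, def, reg)$value)
  }
})

test_that("every produced score lies inside its printed range", {
  reg <- test_registry()
  defs <- scale_definitions()
  for (seed in c(3, 17)) {
    recs <- random_records(250, "MH", p_missing = 0.2, seed = seed)
    sc <- score_scales(recs, reg)
    sc <- dplyr::filter(sc, !is.na(.data$value))
    for (s in unique(sc$scale)) {
      v <- sc$value[sc$scale == s]
      expect_true(all(v >= defs[[s]]$out_min & v <= defs[[s]]$out_max),
                  label = paste(s, "seed", seed))
    }
  }
})

test_that("sum scales are monotone and permutation invariant in components", {
  reg <- test_registry()
  def <- scale_definitions()$dsi
  rec <- random_records(50, "MH", seed = 5)
  base <- score_sum_scale(rec, def, reg)$value
  for (cc in def$components) {
    bumped <- rec
    room <- bumped[[cc]] < max(registry_items(reg)$max_code[
      registry_items(reg)$item_code == cc])
    bumped[[cc]] <- bumped[[cc]] + as.integer(room)
    got <- score_sum_scale(bumped, def, reg)$value
    expect_identical(got - base, as.integer(room), label = cc)
  }
  shuffled <- def
  shuffled$components <- rev(def$components)
  expect_identical(score_sum_scale(rec, shuffled, reg)$value, base)
})

test_that("missing components yield missing scores unless prorated", {
  reg <- test_registry()
  def <- scale_definitions()$pss
  rec <- full_record("MH", 2L)
  rec$hallucinations <- NA_integer_
  out <- score_sum_scale(rec, def, reg)
  expect_true(is.na(out$value))
  expect_false(out$complete)
  expect_equal(out$n_missing_components, 1L)
  # prorating: observed sum 6 over 3 of 4 items -> 8
  pro <- score_sum_scale(rec, def, reg, prorate = TRUE)
  expect_equal(pro$value, 8L)
  # round-half-even: observed 3 of 4, sum 5 -> 5 * 4/3 = 6.67 -> 7
  rec2 <- rec
  rec2$command_hallucinations <- 1L
  expect_equal(score_sum_scale(rec2, scale_definitions()$pss, reg,
                               prorate = TRUE)$value, 7L)
  # all missing stays missing even when prorating
  empty <- tibble::tibble(person_id = "p", instrument = "MH",
                          reason = "admission", date = as.Date("2020-01-01"))
  expect_true(is.na(score_sum_scale(empty, def, reg, prorate = TRUE)$value))
})

test_that("scale applicability follows the instrument matrix", {
  reg <- test_registry()
  # BMHS: only the positive-symptoms scale
  bm <- full_record("BMHS", 1L)
  sc <- score_scales(bm, reg)
  expect_equal(sc$scale, "pss")
  # ESP: nine scales (no ADL, IADL, CAGE or PAIN)
  esp <- full_record("ESP", 1L)
  sc <- score_scales(esp, reg)
  expect_setequal(sc$scale, c("abs", "negsym", "dsi", "mania", "pss",
                              "cps", "rho", "sci", "sss"))
  # MH with full responses: all thirteen
  mh <- full_record("MH", 1L)
  sc <- score_scales(mh, reg)
  expect_equal(nrow(sc), 13)
  expect_true(all(!is.na(sc$value)))
  # empty responses: all scores missing, never zero
  empty <- tibble::tibble(person_id = "p", instrument = "MH",
                          reason = "admission", date = as.Date("2020-01-01"))
  sc <- score_scales(empty, reg)
  expect_equal(nrow(sc), 13)
  expect_true(all(is.na(sc$value)))
  expect_true(all(!sc$complete))
})

test_that("scoring a scale on an instrument lacking its components errors", {
  reg <- test_registry()
  bm <- full_record("BMHS", 1L)
  expect_error(score_sum_scale(bm, scale_definitions()$iadl, reg),
               "mismatch")
})

test_that("malformed scale definitions are rejected at load time", {
  # tree referencing an undeclared variable
  bad_tree <- mhassess:::new_scale_def(
    "bad", "Bad", "decision_tree", components = "hallucinations",
    instruments = "MH", out_min = 0L, out_max = 6L,
    tree = mhassess:::tree_node("delusions", 1L, mhassess:::tree_leaf(6L),
                                mhassess:::tree_leaf(0L)))
  expect_error(mhassess:::validate_scale_defs(list(bad_tree)),
               "neither a component nor a declared sub-scale")
  # sum range inconsistent with component coding
  bad_sum <- mhassess:::new_scale_def(
    "bad2", "Bad2", "sum", components = c("hallucinations", "delusions"),
    instruments = "MH", out_min = 0L, out_max = 5L)
  expect_error(mhassess:::validate_scale_defs(list(bad_sum)),
               "component maxima")
})
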