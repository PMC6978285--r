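# Shared fixtures and independent oracles for the test suite.

test_registry <- function() mh_registry()

# One record with every item of an instrument set to a given code
# (capped at each item's maximum).
full_record <- function(instrument, code = 0L, registry = test_registry()) {
  items <- registry_items(registry, instrument)
  vals <- pmin(code, items$max_code)
  rec <- tibble::tibble(person_id = "p1", instrument = instrument,
                        reason = "admission", date = as.Date("2020-01-01"))
  for (i in seq_len(nrow(items))) rec[[items$item_code[i]]] <- as.integer(vals[i])
  rec
}

# Random valid records for an instrument (each item uniform over its range,
# with a share of missing responses).
random_records <- function(n, instrument = "MH", p_missing = 0,
                           registry = test_registry(), seed = 1) {
  withr::with_seed(seed, {
    items <- registry_items(registry, instrument)
    rec <- tibble::tibble(
      person_id = sprintf("p%04d", seq_len(n)), instrument = instrument,
      reason = "admission",
      date = as.Date("2020-01-01") + sample(0:364, n, replace = TRUE))
    for (i in seq_len(nrow(items))) {
      v <- sample(items$min_code[i]:items$max_code[i], n, replace = TRUE)
      if (p_missing > 0) v[stats::runif(n) < p_missing] <- NA_integer_
      rec[[items$item_code[i]]] <- as.integer(v)
    }
    rec
  })
}

# --- independent oracles ------------------------------------------------

# Naive per-record summation over a sum scale's components.
oracle_sum_scale <- function(records, def) {
  vapply(seq_len(nrow(records)), function(i) {
    tot <- 0L
    for (cc in def$components) {
      v <- if (cc %in% names(records)) records[[cc]][i] else NA_integer_
      if (!is.null(def$component_max) && cc %in% names(def$component_max)) {
        v <- min(v, def$component_max[[cc]])
      }
      if (is.na(v)) return(NA_integer_)
      tot <- tot + as.integer(v)
    }
    tot
  }, integer(1))
}

# Scalar tree evaluation by walking conditions one record at a time
# (independent of the vectorized engine).
oracle_tree_scalar <- function(node, values) {
  if (!is.null(node$score)) return(node$score)
  v <- values[[node$var]]
  if (is.null(v) || is.na(v)) return(NA_integer_)
  if (v >= node$value) oracle_tree_scalar(node$yes, values)
  else oracle_tree_scalar(node$no, values)
}

# Spreadsheet-style alpha: explicit sums, no var() shortcuts.
oracle_alpha <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  svar <- function(x) sum((x - sum(x) / n)^2) / (n - 1)
  tot <- rowSums(m)
  (k / (k - 1)) * (1 - sum(apply(m, 2, svar)) / svar(tot))
}

# Brute-force weighted kappa over all k x k cells.
oracle_kappa <- function(tab, weights = "quadratic") {
  k <- nrow(tab); n <- sum(tab)
  num <- 0; den <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    d <- abs(i - j) / (k - 1)
    w <- if (weights == "quadratic") d^2 else d
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    num <- num + w * tab[i, j]
    den <- den + w * e
  }
  1 - num / den
}

# O(n^2) pairwise concordance count.
oracle_c <- function(outcome, score) {
  cases <- score[outcome == 1]
  controls <- score[outcome == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}

# Direct enumeration of the two QI outcome definitions.
oracle_qi <- function(baseline, followup, smax, indicator) {
  num <- 0L; den <- 0L
  for (i in seq_along(baseline)) {
    if (is.na(baseline[i]) || is.na(followup[i])) next
    if (indicator == "improvement") {
      if (baseline[i] > 0) {
        den <- den + 1L
        if (followup[i] < baseline[i]) num <- num + 1L
      }
    } else {
      if (baseline[i] < smax) {
        den <- den + 1L
        if (followup[i] >= baseline[i]) num <- num + 1L
      }
    }
  }
  c(num = num, den = den)
}
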