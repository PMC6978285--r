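test_that("alpha is 1 for parallel items, ~0 for independent items", {
  x <- rep(1:6, 4)
  m <- cbind(a = x, b = x)
  expect_equal(cronbach_alpha(m), 1)
  withr::with_seed(101, {
    ind <- matrix(sample(0:3, 5 * 5000, replace = TRUE), ncol = 5)
    expect_lt(abs(cronbach_alpha(ind)), 0.05)
  })
})

test_that("alpha matches a spreadsheet-style brute-force computation", {
  m <- matrix(c(2, 3, 3, 1,
                0, 1, 1, 0,
                3, 3, 2, 2,
                1, 2, 1, 1,
                2, 2, 3, 2,
                0, 0, 1, 1), ncol = 4, byrow = TRUE)
  expect_equal(cronbach_alpha(m), oracle_alpha(m), tolerance = 1e-12)
  withr::with_seed(7, {
    for (i in 1:50) {
      r <- matrix(sample(0:4, 6 * 20, replace = TRUE), ncol = 6)
      if (stats::var(rowSums(r)) == 0) next
      expect_equal(cronbach_alpha(r), oracle_alpha(r), tolerance = 1e-12)
    }
  })
})

test_that("alpha rejects degenerate inputs", {
  expect_error(cronbach_alpha(matrix(1:10, ncol = 1)), "at least 2 items")
  const <- cbind(c(1, 2, 1, 2), c(2, 1, 2, 1))  # total is constant
  expect_error(cronbach_alpha(const), "variance is zero")
  withna <- cbind(c(1, NA, 2), c(2, 1, 1))
  expect_error(cronbach_alpha(withna), "complete cases")
})

test_that("alpha approaches the Spearman-Brown value for exchangeable items", {
  withr::with_seed(55, {
    k <- 5; r <- 0.5; n <- 20000
    lambda <- sqrt(r)
    theta <- stats::rnorm(n)
    m <- vapply(1:k, function(j) lambda * theta + sqrt(1 - r) * stats::rnorm(n),
                numeric(n))
    expect_equal(cronbach_alpha(m), k * r / (1 + (k - 1) * r), tolerance = 0.02)
  })
})

test_that("weighted kappa equals hand computation and its boundary values", {
  diag_tab <- diag(c(30, 20, 10))
  expect_equal(weighted_kappa(diag_tab), 1)
  # independence: outer product of margins -> exactly chance agreement
  p <- c(0.5, 0.3, 0.2); q <- c(0.2, 0.5, 0.3)
  indep <- outer(p, q) * 100
  expect_equal(weighted_kappa(indep), 0, tolerance = 1e-12)
  expect_equal(weighted_kappa(indep, weights = "linear"), 0, tolerance = 1e-12)
  # 3x3 with one off-diagonal cell
  tab <- diag(c(40, 30, 20)); tab[1, 2] <- 10
  expect_equal(weighted_kappa(tab), oracle_kappa(tab), tolerance = 1e-12)
  expect_equal(weighted_kappa(tab, weights = "linear"),
               oracle_kappa(tab, "linear"), tolerance = 1e-12)
  withr::with_seed(19, {
    for (i in 1:50) {
      k <- sample(2:6, 1)
      t2 <- matrix(stats::rpois(k * k, 5), ncol = k)
      if (sum(t2) == 0) next
      expect_equal(weighted_kappa(t2), oracle_kappa(t2), tolerance = 1e-12)
    }
  })
})

test_that("quadratic-weighted kappa on a 2x2 table equals unweighted kappa", {
  unweighted_kappa <- function(m) {
    n <- sum(m)
    po <- sum(diag(m)) / n
    pe <- sum(rowSums(m) * colSums(m)) / n^2
    (po - pe) / (1 - pe)
  }
  withr::with_seed(20, {
    for (i in 1:25) {
      m <- matrix(stats::rpois(4, 10) + 1, 2)
      expect_equal(weighted_kappa(m), unweighted_kappa(m), tolerance = 1e-12)
    }
  })
})

test_that("kappa interfaces agree and degenerate tables error", {
  withr::with_seed(3, {
    a <- sample(0:3, 200, replace = TRUE)
    b <- pmin(pmax(a + sample(-1:1, 200, replace = TRUE), 0), 3)
    tab <- table(factor(a, levels = 0:3), factor(b, levels = 0:3))
    expect_equal(weighted_kappa(a, b, k = 4), weighted_kappa(unclass(tab)))
  })
  all_same <- matrix(0, 3, 3); all_same[2, 2] <- 50
  expect_error(weighted_kappa(all_same), "expected disagreement is zero")
})

test_that("the c-statistic equals exhaustive pair counting", {
  y <- c(rep(1, 5), rep(0, 5))
  expect_equal(c_statistic(y, c(6:10, 1:5)), 1)
  expect_equal(c_statistic(y, rep(2, 10)), 0.5)
  withr::with_seed(77, {
    for (i in 1:20) {
      n <- 200
      y <- stats::rbinom(n, 1, 0.4)
      if (all(y == 0) || all(y == 1)) next
      s <- sample(0:8, n, replace = TRUE)  # heavy ties
      expect_equal(c_statistic(y, s), oracle_c(y, s), tolerance = 1e-12)
      # invariance under strictly increasing transforms
      expect_equal(c_statistic(y, exp(s / 2)), c_statistic(y, s))
    }
  })
  expect_error(c_statistic(rep(1, 10), 1:10), "both outcome classes")
})

test_that("convergent validity recovers configured band log-odds", {
  withr::with_seed(123, {
    n <- 10000
    score <- sample(0:12, n, replace = TRUE)
    band <- findInterval(score, c(-Inf, 1, 3, 6))
    lo <- c(0, 0.8, 1.4, 2.0)
    y <- stats::rbinom(n, 1, stats::plogis(-1.5 + lo[band]))
    fit <- convergent_validity(tibble::tibble(dx = y, pss = score),
                               "dx", bands = list(pss = c(1, 3, 6)))
    td <- tidy(fit)
    est <- td$estimate[!td$reference]
    se <- (log(td$conf.high) - log(td$conf.low))[!td$reference] / (2 * 1.96)
    expect_true(all(abs(est - lo[-1]) < 3 * se))
    expect_gt(glance(fit)$c, 0.5)
    expect_equal(td$odds_ratio[td$reference], 1)
  })
})

test_that("confidence intervals cover the null when there is no association", {
  withr::with_seed(321, {
    reps <- 100
    covered <- c(0L, 0L, 0L)   # per non-reference band
    for (i in seq_len(reps)) {
      n <- 600
      score <- sample(0:12, n, replace = TRUE)
      y <- stats::rbinom(n, 1, 0.3)
      fit <- convergent_validity(tibble::tibble(dx = y, s = score),
                                 "dx", bands = list(s = c(1, 3, 6)))
      td <- tidy(fit)
      hit <- td$conf.low[!td$reference] <= 1 & td$conf.high[!td$reference] >= 1
      covered <- covered + hit
    }
    # each nominal-95% interval should cover the null in >= 90% of replicates
    expect_true(all(covered / reps >= 0.90))
  })
})

test_that("empty bands are dropped with a warning and listwise deletion is logged", {
  withr::with_seed(9, {
    d <- tibble::tibble(dx = stats::rbinom(200, 1, 0.4),
                        s = sample(0:3, 200, replace = TRUE))
    d$s[1:10] <- NA
    expect_warning(
      fit <- convergent_validity(d, "dx", bands = list(s = c(1, 2, 8))),
      "empty band")
    expect_equal(fit$n_dropped, 10)
  })
})
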