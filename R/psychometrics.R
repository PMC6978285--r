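# Psychometric evaluation: internal consistency, weighted inter-rater
# agreement, and banded-covariate convergent validity.

#' Cronbach's alpha
#'
#' Internal consistency of a multi-item scale:
#' alpha = k/(k-1) * (1 - sum_i var(item_i) / var(total)).
#' Sample variances use the n-1 divisor throughout.  Alpha is at most 1
#' and may be negative for items that covary negatively.
#'
#' @param items A data frame or matrix of complete-case item responses,
#'   one column per item (at least 2 columns and 2 rows, no missing cells).
#' @return The alpha coefficient (length-1 numeric).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(500), ncol = 5)
#' cronbach_alpha(x + rnorm(100))  # correlated items, high alpha
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (!is.numeric(m)) stop("item matrix must be numeric", call. = FALSE)
  if (anyNA(m)) stop("item matrix must be complete cases (no missing cells)",
                     call. = FALSE)
  k <- ncol(m)
  if (k < 2L) stop("alpha requires at least 2 items", call. = FALSE)
  if (nrow(m) < 2L) stop("alpha requires at least 2 observations", call. = FALSE)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) {
    stop("undefined alpha: total-score variance is zero", call. = FALSE)
  }
  item_var <- sum(apply(m, 2, stats::var))
  (k / (k - 1)) * (1 - item_var / total_var)
}

#' Weighted kappa
#'
#' Chance-corrected inter-rater agreement for ordinal categories with
#' distance-based disagreement weights:
#' kappa_w = 1 - sum(w * O) / sum(w * E), with w_ij = ((i-j)/(k-1))^2
#' (quadratic, the default) or |i-j|/(k-1) (linear), and E the outer
#' product of the margins.  Equals 1 iff all mass is on the diagonal.
#'
#' @param x Either a k x k contingency table/matrix of counts
#'   (rater A in rows, rater B in columns), or a vector of rater-A codes
#'   (then `y` must give rater B's codes on the same scale).
#' @param y Optional rater-B vector when `x` is a vector.
#' @param weights `"quadratic"` or `"linear"`.
#' @param k Number of ordinal categories when `x`/`y` are vectors
#'   (defaults to the observed range).
#' @return The weighted kappa (length-1 numeric).
#' @export
weighted_kappa <- function(x, y = NULL, weights = c("quadratic", "linear"),
                           k = NULL) {
  weights <- match.arg(weights)
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    lev <- if (is.null(k)) seq(min(x, y), max(x, y)) else seq_len(k) - 1L
    tab <- table(factor(x, levels = lev), factor(y, levels = lev))
    m <- unclass(as.matrix(tab))
  } else {
    m <- as.matrix(x)
  }
  if (nrow(m) != ncol(m)) stop("agreement table must be square", call. = FALSE)
  if (any(m < 0)) stop("agreement counts must be non-negative", call. = FALSE)
  n <- sum(m)
  if (n <= 0) stop("agreement table has no observations", call. = FALSE)
  kk <- nrow(m)
  if (kk < 2L) stop("kappa requires at least 2 categories", call. = FALSE)
  idx <- seq_len(kk)
  d <- abs(outer(idx, idx, "-")) / (kk - 1)
  w <- if (weights == "quadratic") d^2 else d
  e <- outer(rowSums(m), colSums(m)) / n
  denom <- sum(w * e)
  if (denom == 0) {
    stop("undefined kappa: expected disagreement is zero", call. = FALSE)
  }
  1 - sum(w * m) / denom
}

#' Concordance statistic (c / AUC)
#'
#' Probability that a randomly chosen case outranks a randomly chosen
#' control on the score, with ties counted half:
#' c = (concordant + 0.5 * tied) / (cases x controls).  Computed via the
#' rank formulation, so it is invariant to strictly increasing transforms
#' of the score.
#'
#' @param outcome Binary vector (0/1 or logical); both classes required.
#' @param score Numeric score vector of the same length.
#' @return c in \[0, 1\].
#' @export
c_statistic <- function(outcome, score) {
  outcome <- as.integer(as.logical(outcome))
  stopifnot(length(outcome) == length(score))
  ok <- !is.na(outcome) & !is.na(score)
  outcome <- outcome[ok]; score <- score[ok]
  n1 <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("c-statistic requires both outcome classes", call. = FALSE)
  }
  r <- rank(score)  # midranks handle ties as half-concordant
  (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Banded convergent validity
#'
#' Tests whether hallmark symptom scales are associated with the presence
#' of a provisional diagnosis: the scale is cut into ordinal bands (the
#' lowest band is the reference), the diagnosis flag is regressed on the
#' band indicators (plus any additional adjusters) by maximum-likelihood
#' logistic regression, and the association is summarized as per-band
#' odds ratios with Wald 95\% confidence intervals together with the
#' concordance statistic of the fitted scores.
#'
#' Analysis is complete-case; the number of rows dropped for missingness
#' is recorded in the result.  Empty bands are dropped with a warning;
#' a band separated perfectly from the reference is flagged and its
#' confidence interval reported as unbounded.
#'
#' @param data Tibble holding the outcome flag and the banded covariates
#'   (typically records joined with wide scale scores).
#' @param outcome Name of the binary diagnosis column.
#' @param bands Named list: for each covariate column, the cut points
#'   given as the lower edges of the non-reference bands (e.g.
#'   `list(dsi = c(1, 4, 8))` for bands 0 / 1-3 / 4-7 / 8-15).
#' @param adjust Character vector of additional covariate columns entered
#'   linearly (default none).
#' @return An object of class `mh_validity`; see [tidy.mh_validity()] and
#'   [glance.mh_validity()].
#' @export
convergent_validity <- function(data, outcome, bands, adjust = character()) {
  data <- tibble::as_tibble(data)
  stopifnot(outcome %in% names(data), length(bands) >= 1L)
  for (v in c(names(bands), adjust)) {
    if (!v %in% names(data)) stop("column not found: ", v, call. = FALSE)
  }
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(stats::na.omit(y) %in% 0:1)) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }

  model_df <- tibble::tibble(.y = y)
  band_levels <- list()
  for (v in names(bands)) {
    edges <- sort(unique(as.numeric(bands[[v]])))
    breaks <- c(-Inf, edges, Inf)
    labs <- band_labels(edges, data[[v]])
    f <- cut(as.numeric(data[[v]]), breaks = breaks, labels = labs,
             right = FALSE)
    present <- labs %in% levels(droplevels(f))
    if (!all(present)) {
      warning("dropping empty band(s) of '", v, "': ",
              paste(labs[!present], collapse = ", "), call. = FALSE)
      f <- droplevels(f)
    }
    model_df[[v]] <- f
    band_levels[[v]] <- levels(f)
  }
  for (v in adjust) model_df[[v]] <- data[[v]]

  n_total <- nrow(model_df)
  cc <- stats::complete.cases(model_df)
  model_df <- model_df[cc, , drop = FALSE]
  fit <- stats::glm(.y ~ ., data = model_df, family = stats::binomial())
  separated <- !fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (separated) {
    warning("possible perfect separation: some interval(s) reported as unbounded",
            call. = FALSE)
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  cstat <- c_statistic(model_df$.y, stats::fitted(fit))
  structure(
    list(fit = fit, outcome = outcome, bands = bands,
         band_levels = band_levels, adjust = adjust,
         coef = est, se = se, c = cstat,
         n = nrow(model_df), n_dropped = n_total - nrow(model_df),
         separated = separated),
    class = "mh_validity"
  )
}

band_labels <- function(edges, x) {
  lo <- c(min(c(0, floor(min(x, na.rm = TRUE)))), edges)
  hi <- c(edges - 1, max(c(edges[length(edges)], ceiling(max(x, na.rm = TRUE)))))
  ifelse(lo == hi, as.character(lo), paste0(lo, "-", hi))
}

#' @export
print.mh_validity <- function(x, ...) {
  cat(sprintf("<mh_validity> outcome '%s', n = %d (dropped %d), c = %.3f\n",
              x$outcome, x$n, x$n_dropped, x$c))
  print(tidy(x))
  invisible(x)
}

#' Tidy a convergent-validity fit
#'
#' @param x An `mh_validity` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `covariate`, `band`,
#'   `estimate` (log-odds), `odds_ratio`, `conf.low`, `conf.high`
#'   (Wald 95\% interval on the OR scale; the reference band appears with
#'   `odds_ratio = 1` and a degenerate interval).
#' @export
tidy.mh_validity <- function(x, ...) {
  z <- stats::qnorm(0.975)
  rows <- list()
  for (v in names(x$band_levels)) {
    levs <- x$band_levels[[v]]
    rows[[paste0(v, ".ref")]] <- tibble::tibble(
      covariate = v, band = levs[1], reference = TRUE,
      estimate = 0, odds_ratio = 1, conf.low = 1, conf.high = 1
    )
    for (lev in levs[-1]) {
      term <- paste0(v, lev)
      est <- x$coef[[term]]
      se <- x$se[[term]]
      unbounded <- x$separated && abs(est) > 15
      rows[[term]] <- tibble::tibble(
        covariate = v, band = lev, reference = FALSE,
        estimate = est, odds_ratio = exp(est),
        conf.low = if (unbounded) 0 else exp(est - z * se),
        conf.high = if (unbounded) Inf else exp(est + z * se)
      )
    }
  }
  for (v in x$adjust) {
    terms <- grep(paste0("^", v), names(x$coef), value = TRUE)
    for (term in terms) {
      est <- x$coef[[term]]
      se <- x$se[[term]]
      rows[[term]] <- tibble::tibble(
        covariate = v, band = sub(paste0("^", v), "", term), reference = FALSE,
        estimate = est, odds_ratio = exp(est),
        conf.low = exp(est - z * se), conf.high = exp(est + z * se)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Glance at a convergent-validity fit
#'
#' @param x An `mh_validity` object.
#' @param ... Unused.
#' @return One-row tibble: `outcome`, `n`, `n_dropped`, `c`, `separated`,
#'   `deviance`, `aic`.
#' @export
glance.mh_validity <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n = x$n, n_dropped = x$n_dropped, c = x$c,
    separated = x$separated,
    deviance = stats::deviance(x$fit), aic = stats::AIC(x$fit)
  )
}
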