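# Synthetic cohort generator.
#
# Latent single-factor model per scale block: each person draws a latent
# trait theta ~ N(0,1) per block (shifted by group effects in latent SD
# units), each item realizes y* = lambda * theta + sqrt(1-lambda^2) * eps
# and is discretized through fixed thresholds into its ordinal coding
# range.  Item loadings are calibrated so that Cronbach's alpha of the
# *observed ordinal items* matches the block's target, by dividing the
# Spearman-Brown inter-item correlation by the squared
# discretization-attenuation factor (see the methods vignette).
# Diagnosis flags are drawn from logistic models on observed scale-score
# bands, so banded convergent-validity analyses recover the configured
# log-odds by construction.  One global seed governs all draws; each
# generator phase derives its own sub-seed deterministically.

derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) + 1009L * as.integer(offset)
}

#' Inter-item correlation and loading for a target alpha
#'
#' Inverts the Spearman-Brown relation alpha = k r / (1 + (k-1) r):
#' r = alpha / (k - alpha (k-1)), lambda = sqrt(r).  This is the latent,
#' continuous-item solution; the cohort generator additionally corrects
#' for ordinal discretization.
#'
#' @param target_alpha Desired alpha, in (0, 1).
#' @param k Number of items (>= 2).
#' @return List with `r` (inter-item correlation) and `lambda` (loading).
#' @export
#' @examples
#' s <- solve_loading(0.85, 5)
#' 5 * s$r / (1 + 4 * s$r)  # 0.85
solve_loading <- function(target_alpha, k) {
  stopifnot(k >= 2)
  if (!is.finite(target_alpha) || target_alpha <= 0 || target_alpha >= 1) {
    stop("target alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  r <- target_alpha / (k - target_alpha * (k - 1))
  if (r >= 1) stop("target alpha unreachable: implied r >= 1", call. = FALSE)
  list(r = r, lambda = sqrt(r))
}

# Equal-quantile thresholds for an m+1 category item; "skewed" presets
# emulate the zero-inflation of clinical symptom distributions.
item_thresholds <- function(max_code, style = c("uniform", "skewed")) {
  style <- match.arg(style)
  j <- seq_len(max_code)
  if (style == "uniform") {
    stats::qnorm(j / (max_code + 1))
  } else {
    stats::qnorm(0.55 + 0.4 * j / (max_code + 1))
  }
}

# Attenuation factor A = corr(discretized item, latent y*):
# A = sum_j phi(tau_j) / sd(discretized).
discretization_attenuation <- function(thresholds) {
  p_exceed <- 1 - stats::pnorm(thresholds)   # P(X >= j)
  mu <- sum(p_exceed)
  exsq <- sum((2 * seq_along(thresholds) - 1) * p_exceed)
  v <- exsq - mu^2
  sum(stats::dnorm(thresholds)) / sqrt(v)
}

# Loading that yields the target alpha on the observed ordinal items.
calibrated_loading <- function(target_alpha, k, thresholds) {
  r <- solve_loading(target_alpha, k)$r
  a2 <- discretization_attenuation(thresholds)^2
  r_lat <- r / a2
  if (r_lat >= 1) {
    stop("target alpha unreachable after discretization correction", call. = FALSE)
  }
  sqrt(r_lat)
}

discretize <- function(ystar, thresholds) {
  out <- integer(length(ystar))
  for (tau in thresholds) out <- out + as.integer(ystar > tau)
  out
}

#' Simulation configuration
#'
#' Assembles the generator's parameters with defaults chosen to emulate a
#' plausible inpatient cohort: scale blocks with target internal
#' consistencies in the published 0.7-0.9 range, a homeless prevalence of
#' 15\% with latent-severity shifts concentrated on psychosis, self-care
#' and economic blocks, diagnosis flags linked to scale-score bands, a
#' two-rater perturbation model and an admission/follow-up longitudinal
#' model with group-dependent improvement.
#'
#' @param n Number of persons.
#' @param instrument Instrument code for emitted records (default MH).
#' @param p_homeless Homeless prevalence.
#' @param scales Named list of blocks: each `list(items = <codes>,
#'   target_alpha = <value>)`.  Defaults cover the sum scales.
#' @param aux_items Named list of single-item specs
#'   `list(block = <latent name or NA>, loading = <value>)` for
#'   tree/CAP inputs.
#' @param homeless_shift Named numeric: latent-mean shift (SD units) per
#'   block for homeless persons.
#' @param dx_links Named list of diagnosis links: each
#'   `list(scale = <scale name>, edges = <lower band edges>,
#'   log_odds = <per-band log odds, reference first (0)>,
#'   intercept = <reference log odds>)`.
#' @param rater_noise Probability that the second rater records an
#'   adjacent category.
#' @param longitudinal List: `rho` (latent autocorrelation),
#'   `delta` (improvement, latent SD), `delta_homeless_deficit`
#'   (reduction of delta for homeless persons), `improve_blocks`
#'   (blocks receiving delta), `p_lost` (admissions with no follow-up).
#' @param threshold_style `"uniform"` (equal category use) or `"skewed"`
#'   (zero-inflated symptom distributions).
#' @param years Calendar years over which admissions are spread.
#' @return A list of class `mh_sim_config`.
#' @export
sim_config <- function(n = 2000,
                       instrument = "MH",
                       p_homeless = 0.15,
                       scales = NULL,
                       aux_items = NULL,
                       homeless_shift = NULL,
                       dx_links = NULL,
                       rater_noise = 0.10,
                       longitudinal = NULL,
                       threshold_style = c("uniform", "skewed"),
                       years = 2016:2017) {
  threshold_style <- match.arg(threshold_style)
  defs <- scale_definitions(extras = TRUE)
  if (is.null(scales)) {
    alpha_default <- c(pss = 0.72, dsi = 0.80, negsym = 0.86, mania = 0.75,
                       abs = 0.72, cage = 0.75, adl = 0.85, iadl = 0.88,
                       pain = 0.80, sws = 0.80)
    scales <- lapply(names(alpha_default), function(s) {
      list(items = defs[[s]]$components, target_alpha = unname(alpha_default[s]))
    })
    names(scales) <- names(alpha_default)
  }
  for (s in names(scales)) {
    a <- scales[[s]]$target_alpha
    if (!is.finite(a) || a <= 0 || a >= 1) {
      stop("target alpha for block '", s, "' must be in (0,1)", call. = FALSE)
    }
  }
  if (is.null(aux_items)) {
    aux_items <- list(
      daily_decision_making       = list(block = "cog", loading = 0.80),
      short_term_memory           = list(block = "cog", loading = 0.80),
      making_self_understood      = list(block = "cog", loading = 0.70),
      insight_problem             = list(block = "pss", loading = 0.60),
      decreased_energy            = list(block = "dsi", loading = 0.60),
      sleep_disturbance           = list(block = "dsi", loading = 0.50),
      self_harm_ideation          = list(block = "self_harm", loading = 0.80),
      suicide_attempts            = list(block = "self_harm", loading = 0.70),
      suicide_plan                = list(block = "self_harm", loading = 0.70),
      others_concerned            = list(block = "self_harm", loading = 0.60),
      violence_extreme_behavior   = list(block = "harm_others", loading = 0.75),
      violent_ideation            = list(block = "harm_others", loading = 0.70),
      intimidation_threats        = list(block = "harm_others", loading = 0.70),
      withdrawal_symptoms         = list(block = "cage", loading = 0.60),
      smokes_daily                = list(block = "cage", loading = 0.40),
      count_substances            = list(block = "cage", loading = 0.60),
      misuse_prescription_meds    = list(block = "cage", loading = 0.50),
      days_drank_intox            = list(block = "cage", loading = 0.60),
      five_plus_drinks            = list(block = "cage", loading = 0.60),
      conflict_with_others        = list(block = "sws", loading = 0.50),
      informal_support_problem    = list(block = "sws", loading = 0.50),
      lack_of_discharge_support   = list(block = "sws", loading = 0.40),
      economic_hardship           = list(block = "econ", loading = 0.70),
      education_employment_risk   = list(block = "econ", loading = 0.70),
      prior_hospitalizations      = list(block = "pss", loading = 0.50),
      control_intervention_history = list(block = "abs", loading = 0.60),
      falls                       = list(block = "adl", loading = 0.50),
      stopped_meds                = list(block = NA, loading = 0),
      med_adherence_problem       = list(block = NA, loading = 0),
      bmi_problem                 = list(block = NA, loading = 0),
      eating_behavior             = list(block = NA, loading = 0),
      low_physical_activity       = list(block = NA, loading = 0),
      traumatic_event_fear        = list(block = NA, loading = 0),
      recent_trauma               = list(block = NA, loading = 0)
    )
  }
  if (is.null(homeless_shift)) {
    homeless_shift <- c(pss = 0.5, dsi = 0.3, negsym = 0.3, abs = 0.3,
                        adl = 0.3, iadl = 0.5, sws = 0.4, cage = 0.4,
                        harm_others = 0.3, self_harm = 0.3, cog = 0.2,
                        econ = 0.8)
  }
  if (is.null(dx_links)) {
    dx_links <- list(
      dx_psychosis = list(scale = "pss", edges = c(1, 3, 6),
                          log_odds = c(0, 0.8, 1.4, 2.0), intercept = -2.0),
      dx_depression = list(scale = "dsi", edges = c(1, 4, 8),
                           log_odds = c(0, 0.4, 0.8, 1.3), intercept = -1.5),
      dx_substance = list(scale = "cage", edges = c(1, 2, 4),
                          log_odds = c(0, 1.0, 1.6, 2.2), intercept = -2.0),
      dx_neurocognitive = list(scale = "cps", edges = c(1, 3),
                               log_odds = c(0, 1.5, 2.5), intercept = -3.0)
    )
  }
  if (is.null(longitudinal)) {
    longitudinal <- list(rho = 0.7, delta = 0.8, delta_homeless_deficit = 0.4,
                         improve_blocks = c("pss", "dsi", "iadl"),
                         p_lost = 0.05)
  }
  if (rater_noise < 0 || rater_noise > 1) {
    stop("rater_noise must be a probability", call. = FALSE)
  }
  if (longitudinal$rho < 0 || longitudinal$rho > 1) {
    stop("latent autocorrelation rho must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n = n, instrument = instrument, p_homeless = p_homeless,
         scales = scales, aux_items = aux_items,
         homeless_shift = homeless_shift, dx_links = dx_links,
         rater_noise = rater_noise, longitudinal = longitudinal,
         threshold_style = threshold_style, years = years),
    class = "mh_sim_config"
  )
}

sim_block_names <- function(config) {
  aux_blocks <- unique(stats::na.omit(
    vapply(config$aux_items, function(a) as.character(a$block), "")))
  unique(c(names(config$scales), setdiff(aux_blocks, "NA")))
}

# Draw the latent traits for a cohort (rows = persons, cols = blocks).
draw_latents <- function(n, config, homeless) {
  blocks <- sim_block_names(config)
  theta <- matrix(stats::rnorm(n * length(blocks)), nrow = n,
                  dimnames = list(NULL, blocks))
  for (b in intersect(blocks, names(config$homeless_shift))) {
    theta[, b] <- theta[, b] + config$homeless_shift[[b]] * homeless
  }
  theta
}

# Emit ordinal items from latent traits.
emit_items <- function(theta, config, registry) {
  n <- nrow(theta)
  items <- registry$items
  out <- list()
  for (b in names(config$scales)) {
    spec <- config$scales[[b]]
    k <- length(spec$items)
    for (code in spec$items) {
      m <- items$max_code[items$item_code == code]
      tau <- item_thresholds(m, config$threshold_style)
      lam <- calibrated_loading(spec$target_alpha, k, tau)
      ystar <- lam * theta[, b] + sqrt(1 - lam^2) * stats::rnorm(n)
      out[[code]] <- discretize(ystar, tau)
    }
  }
  for (code in names(config$aux_items)) {
    a <- config$aux_items[[code]]
    m <- items$max_code[items$item_code == code]
    if (!length(m)) stop("aux item not in registry: ", code, call. = FALSE)
    tau <- item_thresholds(m, config$threshold_style)
    ystar <- if (is.na(a$block)) {
      stats::rnorm(n)
    } else {
      a$loading * theta[, a$block] + sqrt(1 - a$loading^2) * stats::rnorm(n)
    }
    out[[code]] <- discretize(ystar, tau)
  }
  tibble::as_tibble(out)
}

draw_covariates <- function(n, config) {
  tibble::tibble(
    age = pmin(pmax(round(stats::rnorm(n, 42, 14)), 18), 90),
    sex = sample(c("F", "M"), n, replace = TRUE),
    homeless = stats::runif(n) < config$p_homeless,
    setting = switch(config$instrument,
                     MH = "inpatient", CMH = "community",
                     ESP = "emergency", BMHS = "police", "other")
  )
}

#' Simulate a synthetic assessment cohort
#'
#' Draws a cross-sectional cohort of admission assessments under the
#' configured latent model: correlated ordinal scale items (calibrated to
#' each block's target alpha), tree and CAP input items, covariates, and
#' diagnosis flags linked to observed scale-score bands.  Fully
#' reproducible: the same seed and configuration yield an identical
#' cohort.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed governing all draws.
#' @param registry An `mh_registry`.
#' @return Tibble of assessment records (one row per person).
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 100), seed = 1)
#' dim(cohort)
simulate_cohort <- function(config = sim_config(), seed = 1,
                            registry = mh_registry()) {
  stopifnot(inherits(config, "mh_sim_config"))
  set.seed(derive_seed(seed, 1L))
  n <- config$n
  cov <- draw_covariates(n, config)
  theta <- draw_latents(n, config, cov$homeless)
  item_tbl <- emit_items(theta, config, registry)
  records <- dplyr::bind_cols(
    tibble::tibble(
      person_id = sprintf("p%06d", seq_len(n)),
      instrument = config$instrument,
      reason = "admission",
      date = as.Date(sprintf("%d-01-01", sample(config$years, n, replace = TRUE))) +
        sample(0:364, n, replace = TRUE)
    ),
    cov, item_tbl
  )
  records <- draw_dx_flags(records, config, registry)
  records
}

draw_dx_flags <- function(records, config, registry) {
  if (!length(config$dx_links)) return(records)
  needed <- unique(vapply(config$dx_links, function(l) l$scale, ""))
  defs <- scale_definitions(extras = TRUE)
  scores <- scores_to_wide(
    score_scales(records, registry, defs = defs[needed]), records)
  for (dx in names(config$dx_links)) {
    l <- config$dx_links[[dx]]
    sc <- scores[[l$scale]]
    band <- findInterval(sc, c(-Inf, l$edges))
    logit <- l$intercept + l$log_odds[band]
    p <- stats::plogis(logit)
    records[[dx]] <- stats::runif(nrow(records)) < p
  }
  records
}

#' Simulate two-rater item observations
#'
#' Generates a cohort and a second rater's codes for every simulated
#' item: with probability `rater_noise` the second rater records an
#' adjacent category (direction at random, clamped to the coding range).
#' With zero noise the raters agree perfectly on every item.
#'
#' @inheritParams simulate_cohort
#' @return Long tibble: `person_id`, `item`, `rater_a`, `rater_b`.
#' @export
simulate_raters <- function(config = sim_config(), seed = 1,
                            registry = mh_registry()) {
  stopifnot(inherits(config, "mh_sim_config"))
  records <- simulate_cohort(config, seed, registry)
  set.seed(derive_seed(seed, 2L))
  item_codes <- c(unlist(lapply(config$scales, `[[`, "items"), use.names = FALSE),
                  names(config$aux_items))
  items <- registry$items
  out <- list()
  for (code in item_codes) {
    a <- records[[code]]
    m <- items$max_code[items$item_code == code]
    flip <- stats::runif(length(a)) < config$rater_noise
    dir <- sample(c(-1L, 1L), length(a), replace = TRUE)
    b <- pmin(pmax(a + flip * dir, 0L), m)
    out[[code]] <- tibble::tibble(person_id = records$person_id, item = code,
                                  rater_a = a, rater_b = as.integer(b))
  }
  dplyr::bind_rows(out)
}

#' Simulate longitudinal admission/follow-up episodes
#'
#' Generates admission assessments, then a follow-up assessment
#' (discharge or 90-day review) for each person not lost to follow-up.
#' Follow-up latents are rho * baseline - delta(group) + noise, where
#' the improvement delta applies to the configured blocks and homeless
#' persons receive `delta - delta_homeless_deficit`, so improvement is
#' group-dependent by construction.
#'
#' @inheritParams simulate_cohort
#' @return Tibble of records with two rows (admission + follow-up) per
#'   retained person, suitable for [pair_followups()].
#' @export
simulate_episodes <- function(config = sim_config(), seed = 1,
                              registry = mh_registry()) {
  stopifnot(inherits(config, "mh_sim_config"))
  set.seed(derive_seed(seed, 3L))
  n <- config$n
  lng <- config$longitudinal
  cov <- draw_covariates(n, config)
  theta1 <- draw_latents(n, config, cov$homeless)
  items1 <- emit_items(theta1, config, registry)

  delta <- rep(lng$delta, n)
  delta[cov$homeless] <- lng$delta - lng$delta_homeless_deficit
  theta2 <- theta1
  for (b in colnames(theta1)) {
    drift <- if (b %in% lng$improve_blocks) delta else 0
    theta2[, b] <- lng$rho * theta1[, b] - drift +
      sqrt(1 - lng$rho^2) * stats::rnorm(n)
  }
  items2 <- emit_items(theta2, config, registry)

  adm_date <- as.Date(sprintf("%d-01-01", sample(config$years, n, replace = TRUE))) +
    sample(0:364, n, replace = TRUE)
  fu_days <- sample(15:85, n, replace = TRUE)
  fu_reason <- sample(c("discharge", "review"), n, replace = TRUE, prob = c(0.7, 0.3))
  lost <- stats::runif(n) < lng$p_lost
  pid <- sprintf("p%06d", seq_len(n))

  adm <- dplyr::bind_cols(
    tibble::tibble(person_id = pid, instrument = config$instrument,
                   reason = "admission", date = adm_date),
    cov, items1)
  fu <- dplyr::bind_cols(
    tibble::tibble(person_id = pid, instrument = config$instrument,
                   reason = fu_reason, date = adm_date + fu_days),
    cov, items2)
  fu <- fu[!lost, , drop = FALSE]
  out <- dplyr::bind_rows(adm, fu)
  out[order(out$person_id, out$date), , drop = FALSE]
}
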