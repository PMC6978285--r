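# mhassess

Tools for working with the interRAI family of adult mental-health
assessment instruments as a *computable system*. The family consists of
four interlocking instruments — the inpatient Mental Health assessment
(MH, 396 items), Community Mental Health (CMH, 405 items, sharing 330
items with the MH), the Emergency Screener for Psychiatry (ESP, a
141-item subset) and the Brief Mental Health Screener used by police
(BMHS, a 46-item subset of the ESP) — plus the summary scales, risk
algorithms, care-planning triggers, quality indicators and per-diem
case-mix weights built on top of them.

The package is aimed at health-services and psychometric researchers who
work with (or study) this assessment architecture but cannot ship the
proprietary instruments themselves. Every *published structural fact* is
reproduced exactly and asserted by construction; every unpublished
component (decision trees, trigger thresholds, the case-mix classifier)
is a documented, replaceable default. A synthetic cohort generator with
controlled statistical structure makes the whole system testable without
clinical data.

## What it computes

* **Registries** (`build_registry()`, `validate_assessments()`,
  `read_assessments()`/`write_assessments()`): item definitions with
  instrument membership, per-domain counts, coding ranges and look-back
  periods; record validation; bit-exact CSV/JSON-lines round trips.
* **Scales** (`score_scales()`): nine parallel-form sum scales (e.g.
  Positive Symptoms 0–12, Depressive Severity 0–15, ADL 0–16, CAGE 0–4)
  and four decision-tree severities 0–6 (Cognitive Performance, Risk of
  Harm to Others, Self-Care, Severity of Self-harm), with the published
  ranges and instrument applicability.
* **CAP triggers** (`evaluate_caps()`, `triggering_rates()`): the
  21-protocol matrix (MH/CMH trigger 20 each, ESP 4), two-level
  monotone trigger rules, stratified triggering rates.
* **Psychometrics**: Cronbach's alpha
  `α = k/(k−1) · (1 − Σᵢ var(xᵢ)/var(Σx))`; weighted kappa
  `κ_w = 1 − ΣwO/ΣwE` with quadratic or linear disagreement weights; the
  concordance statistic `c = P(score_case > score_control) + ½P(tie)`;
  and banded convergent validity — logistic regression of a provisional
  diagnosis on scale-score bands, reported as odds ratios with Wald 95%
  intervals and the model c-statistic (`convergent_validity()`, with
  broom-style `tidy()`/`glance()` methods).
* **Quality indicators** (`pair_followups()`, `compute_qi()`,
  `risk_adjust()`, `qi_trend()`): admission → 90-day/discharge pairing;
  improvement (baseline > 0, follow-up < baseline) and
  failure-to-improve-or-worsening (baseline < max, follow-up ≥ baseline);
  indirect standardization against a pooled logistic risk model,
  `adjusted = observed/expected × pooled`.
* **Case-mix** (`apply_cmi()`, `summarize_cmi_trend()`): pluggable
  grouping functions, ratio-scale case-mix indexes (the demonstration
  table spans the published 8.4:1 spread), admission/discharge trend
  means with 95% CIs and anchored percent change.
* **Synthetic cohorts** (`sim_config()`, `simulate_cohort()`,
  `simulate_raters()`, `simulate_episodes()`): a latent single-factor
  ordinal item model calibrated so observed Cronbach's alpha hits its
  target, homeless latent-severity shifts, diagnosis flags drawn from
  logistic models on score bands, two-rater noise, and longitudinal
  improvement with group-dependent deltas.

## Worked example

```r
library(mhassess)

cohort <- simulate_cohort(sim_config(n = 2000), seed = 42)
score_scales(cohort) |> dplyr::filter(scale == "pss") |> head(3)
#>   person_id instrument reason    date       scale value n_missing_components
#> 1 p000001   MH         admission 2016-04-04 pss      12                    0
#> 2 p000002   MH         admission 2017-08-31 pss       9                    0
#> 3 p000003   MH         admission 2017-04-17 pss       7                    0
```

Each row is one person's Positive Symptoms Scale score (0–12, the sum of
the four psychosis items); `complete` records whether all components were
observed. Internal consistency of the depressive items lands on the
generator's configured target (0.80):

```r
cronbach_alpha(cohort[, scale_definitions()$dsi$components])
#> [1] 0.8068
```

Quality indicators from a longitudinal cohort — the homeless group is
configured to improve less, and the computed rates recover that:

```r
eps   <- simulate_episodes(sim_config(n = 3000), seed = 42)
pairs <- pair_followups(eps, "pss")
compute_qi(pairs, "improvement", by = "homeless")
#>   homeless indicator   scale numerator denominator  rate
#> 1 FALSE    improvement pss        1695        2356 0.719
#> 2 TRUE     improvement pss         230         378 0.608
```

The published case-mix trend arithmetic (admission mean CMIs 1.567 →
1.657):

```r
cmi_percent_change(1.567, 1.657)$display
#> [1] 5.7
```

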