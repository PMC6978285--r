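---
title: "Methods: scales, triggers, indicators and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scales, triggers, indicators and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhassess)
```

mhassess implements the interRAI adult mental-health assessment family as a
computable system: item registries for the inpatient (MH), community (CMH),
emergency (ESP) and police-screener (BMHS) instruments, the summary scales
and decision-tree severity algorithms built on them, clinical assessment
protocol (CAP) triggers, psychometric evaluation procedures, risk-adjusted
quality indicators, and per-diem case-mix summaries. The real instruments
and their clinical content are proprietary; everything here that is
published structure is reproduced exactly, and everything that is not
published is a documented, replaceable default. This vignette explains the
models and the choices behind those defaults.

## The item registry

The four adult instruments have published cardinalities — MH 396 items,
CMH 405, ESP 141, BMHS 46 — and published overlap structure: MH and CMH
share 330 items, the ESP's items are a subset of that shared core, and the
BMHS is a subset of the ESP. Published per-domain item counts exist for 18
domains per instrument. The item codes and wording are proprietary, so the
registry ships a synthetic namespace: clinically named items back every
scale and trigger rule (e.g. `hallucinations`, `daily_decision_making`),
and anonymous filler items complete each domain's printed count.

Three arithmetic facts of the published table cannot be satisfied
simultaneously with a strict item-level subset structure, and the registry
resolves them explicitly:

* Per-domain counts sum *below* each instrument's stated total (e.g. the MH
  domains sum to 331, not 396). The balance is carried by an explicit
  "unclassified" domain, so every printed total and every printed per-domain
  count for MH and CMH is exact.
* The BMHS per-domain counts sum to 47, one above its stated 46-item total.
  The stated instrument total wins; the largest domain allocation
  (administrative and tracking) is trimmed by one.
* The ESP lists six housing items while the MH lists five, which contradicts
  the ESP-within-MH∩CMH subset at domain level. The overflow is carried in
  the unclassified pool; subset instruments take the largest per-domain
  allocation compatible with the subset invariants.

`build_registry()` re-derives and asserts all cardinality and subset
invariants on every construction, so a modified configuration that breaks a
printed fact fails loudly.

Coding ranges follow the family's conventions: symptom-frequency items are
coded 0–3, ADL performance items 0–4, binary indicators 0–1; individual
items deviate where a published scale range requires it (below). Missing
data is *absence* — an item not assessed is absent from the record (`NA` in
the tabular form), never an in-band sentinel, so the scoring engine can
distinguish "not assessed" from "absent symptom". Dates are ISO-8601
calendar dates, and the 90-day reassessment window uses inclusive day
counting.

## Summary scales

Nine parallel-form sum scales and four decision-tree scales are shipped,
with the published output ranges asserted against the registry's coding
ranges at load time. Two published ranges force coding assumptions, both
configurable:

* **Mania** lists seven components with range 0–20; the default codes
  "sleep problems — hypomania" 0–2 and the other six 0–3 (the minimal
  deviation reproducing the printed maximum).
* **IADL Capacity** lists seven components with range 0–30; the default
  codes meal preparation 0–6 and the other six 0–4.

The **Aggressive Behavior Scale** is printed with range 0–8 in one place
and analyzed with bands up to 12 elsewhere; the default uses four items
coded 0–3 (range 0–12), matching the analyzed distributions, with a named
0–8 variant (`scale_definitions(abs_variant = "0-8")`) that caps each
component at 2.

Sum scales perform no imputation by default: any missing component makes
the score missing, with `complete = FALSE` and the missing-component count
reported. An explicit prorating mode rescales the observed sum by
k/(k − n_missing) and rounds half to even.

The four decision-tree scales (Cognitive Performance Scale, Risk of Harm to
Others, Self-Care Index, Severity of Self-harm) output ordinal severities
0–6. Their published descriptions name the components but not the trees.
The shipped trees are therefore *data, not code*: declarative binary trees
over item values and named sub-scale scores, whose every condition is
`var >= cutoff`, whose leaves realize the full 0–6 range, and which can be
replaced wholesale by a licensed specification via `tree =` in the
definition. Conditions touching a missing value on the realized path
propagate missingness unless the node declares a default branch. Scale
applicability follows the published matrix: thirteen scales on MH and CMH,
nine on the ESP (ADL, IADL, CAGE and PAIN are not collected there), and the
Positive Symptoms Scale alone on the BMHS. Inapplicable scales are omitted,
never scored zero.

## CAP triggers

The shipped protocol list reproduces the published matrix: 21 protocols in
five groups; the MH and CMH each trigger 20, differing only on Informal
Support (community) versus Support Systems for Discharge (inpatient); the
ESP triggers the three patient-safety protocols plus Smoking. Trigger
levels (1 or 2 per protocol) match the published level counts.

The trigger *thresholds* are unpublished. The default rules map each safety
protocol to its decision-tree scale (level 2 at score ≥ 4, level 1 at ≥ 1)
and every remaining protocol to a documented threshold on its nearest scale
or item. All rules are conjunctions of `input >= cutoff` conditions, so the
rule system is monotone: raising any input never lowers the triggered
level. Levels are evaluated top-down (level 2 first). The rules live in the
definition table and are explicitly non-canonical.

Triggering rates are reported per protocol, level and stratum with
numerator and denominator. The denominator is all assessed records (with an
`inputs_complete` flag reported per record), since the published material
does not define the denominator; empty strata are undefined, never zero.

## Psychometric procedures

* **Cronbach's alpha**: `(k/(k−1)) (1 − Σ var(item) / var(total))` with the
  sample (n−1) variance divisor throughout — the divisor only matters for
  small fixtures, and the choice is asserted by the brute-force oracle
  tests.
* **Weighted kappa**: `1 − Σ wO / Σ wE` with disagreement weights
  `((i−j)/(k−1))^2` (quadratic, default — the natural choice for ordinal
  codes) or `|i−j|/(k−1)` (linear), expectation from the margin products.
  On a 2×2 table the quadratic form reduces to unweighted kappa.
* **c-statistic**: the probability a random case outranks a random control,
  ties counted half, computed by the midrank formulation (hence invariant
  to strictly increasing score transforms and identical to the O(n²) pair
  count).
* **Convergent validity**: the published analyses relate banded symptom
  scales to provisional diagnoses via odds ratios and a c-statistic. The
  implementation cuts each covariate at configured lower band edges
  (lowest band = reference), fits a maximum-likelihood logistic model of
  the diagnosis flag on the band indicators plus any declared adjusters,
  and reports exponentiated coefficients with Wald 95% intervals and the
  c-statistic of the fitted scores. Analysis is complete-case with a
  logged deletion count; empty bands are dropped with a warning; perfect
  separation is flagged and the affected interval reported unbounded. The
  exact adjustment sets of the published models are not stated, so the
  band configurations are explicit arguments.

## Quality indicators

Admission assessments are paired with the earliest reassessment within 90
days, or the discharge assessment if discharge came sooner; admissions with
neither are excluded and counted. Episodes are bounded by the next
admission; a follow-up dated before its admission marks the episode
non-monotone and it is skipped with a log entry.

Two outcome families are computed per scale:

* **improvement** — denominator: pairs with baseline > 0; event:
  follow-up < baseline;
* **failure to improve or worsening** — denominator: pairs below the scale
  maximum at baseline; event: follow-up ≥ baseline. Because the published
  wording is "failure to improve *or* worsening", the inclusive definition
  is the default; a strict-worsening variant (follow-up > baseline) is
  available behind a flag.

For baselines strictly inside the scale range the two definitions partition
the pairs: exactly one of the two events holds.

The published indicators are risk-adjusted but the method is not published.
The implementation uses indirect standardization, the standard approach for
provider profiling: a logistic model of the event on baseline covariates
(default: age band, sex, homelessness, baseline score band) is fitted on
the pooled eligible pairs; each stratum's expected rate is the mean fitted
probability of its members; and adjusted = (observed / expected) × pooled
rate, clipped to [0, 1] with a flag. An intercept-only model reproduces the
observed rates exactly, which the tests assert.

## Case-mix

The published inpatient case-mix system (SCIPP) classifies with ~100
variables into 47 groups spanning an 8.4:1 range of per-diem case-mix
indexes; the tree is unpublished and explicitly out of scope. The module's
contract is the surrounding machinery: a pluggable deterministic grouping
function, CMI application with unknown-group errors and an
unassignable-record log, and admission/discharge trend summaries (mean,
normal-approximation 95% CI, cell size) with percent change between named
periods displayed to one decimal. A documented toy grouper over six groups
(CMIs 0.5–4.2, reproducing the 8.4:1 spread) supports demonstrations and
tests. The percent-change definition is anchored on the earlier period:
swapping the periods changes the denominator, not just the sign. The
confidence intervals are over persons (whether the published intervals are
over persons or facility means is not stated).

## The synthetic cohort generator

No public data exist for these instruments, so the generator is a
first-class module that produces cohorts with the statistical structure
the other modules assume.

**Latent model.** Each scale block has a single latent factor per person,
`theta ~ N(0, 1)`; item j realizes `y* = lambda * theta +
sqrt(1 − lambda²) * eps` and is discretized through fixed thresholds into
its ordinal range. Default thresholds are equal-quantile
(`qnorm(j/(m+1))`), giving roughly uniform category use; a skewed preset
(`threshold_style = "skewed"`) emulates the zero-inflation of real symptom
distributions. Group effects shift latent means in SD units (default:
homeless shifts concentrated on the psychosis, self-care/function and
economic blocks, so homeless severity and safety-trigger rates exceed the
non-homeless rates by construction).

**Alpha calibration.** The Spearman-Brown inversion
`r = alpha / (k − alpha (k−1))` (exposed as `solve_loading()`) gives the
inter-item correlation that yields a target alpha for *continuous* items.
Discretization attenuates observed correlations: for a discretized standard
normal with thresholds `tau`, the correlation with its latent variable is
`A = Σ phi(tau_j) / sd(X)`, and the correlation of two discretized items is
approximately `r · A²`. The generator therefore uses the latent correlation
`r / A²` (erroring if that exceeds 1), so Cronbach's alpha *of the emitted
ordinal items* lands on the target. At n = 5,000 the measured alphas sit
within ±0.03 of their targets; the approximation carries a small positive
bias (about +0.01 at the default settings), well inside that band.

**Diagnosis links.** Flags are drawn from logistic models on the *observed*
scale-score bands (configured lower edges, reference band log-odds 0), so a
banded convergent-validity analysis with the same edges is exactly the
generating model and recovers the configured log-odds within Monte-Carlo
error — an end-to-end identifiability check, not a tautology, since it
exercises scoring, banding and estimation together.

**Raters and episodes.** The two-rater model perturbs each item to an
adjacent category with a configured probability (zero noise gives kappa = 1
identically). The longitudinal model sets the follow-up latent to
`rho * baseline − delta(group) + sqrt(1 − rho²) * noise`, with the
improvement `delta` applied to the configured blocks and reduced by a
deficit for homeless persons, so homeless failure-to-improve rates are
higher by construction. A configured fraction of admissions receives no
follow-up, exercising the exclusion log.

**Reproducibility.** One global seed governs all draws; each generator
phase (cohort, raters, episodes) derives a fixed sub-seed from it, so the
same seed and configuration yield byte-identical output and the three
generators never share a stream.

**What the generator does not emulate.** Real assessments have structured
missingness, informant effects, site and assessor effects, non-normal
latent structure, and item-level content validity; none of these are
modelled. Passing tests therefore demonstrate that the *algorithms* are
correct and identifiable under a controlled data-generating process — not
that any particular clinical population looks like the synthetic one.

## Numerical and testing choices

Tolerances: closed-form oracles are matched to 1e-10 or better; stochastic
recoveries use Monte-Carlo error bounds (3 SE for coefficient recovery,
±0.03 for alpha at n = 5,000). Test problem sizes were chosen as the
smallest that make the stochastic checks stable: 1,000 random instances per
estimator for oracle equivalence, cohorts of 5,000–20,000 for parameter
recovery and confounding removal, and 50,000 only for the alpha convergence
ladder. Ties in the c-statistic are handled by midranks; prorated sum
scores round half to even; degenerate inputs (zero total variance, empty
outcome classes, expected disagreement zero, empty QI denominators) raise
typed errors rather than returning quiet values.

## Known limitations

* The decision trees, CAP thresholds and the toy case-mix grouper are
  structural defaults, not the licensed algorithms; results computed from
  them are architecturally faithful but numerically non-canonical.
* Band-level convergent-validity models omit the published analyses' exact
  adjustment sets, which are not public.
* The registry's unclassified padding makes instrument totals exact at the
  cost of leaving some items without a clinical domain.
* Risk adjustment supports indirect standardization only; direct
  standardization and hierarchical (shrinkage) profiling are out of scope.
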