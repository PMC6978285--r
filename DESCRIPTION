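Package: mhassess
Title: Scoring, Care-Planning Triggers, Quality Indicators and Case-Mix
    for interRAI-Style Mental Health Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computable model of the interRAI adult mental-health
    assessment family. Provides item registries for the inpatient (MH),
    community (CMH), emergency (ESP) and police-screener (BMHS)
    instruments; summary-scale scoring for parallel-form sum scales and
    configurable decision-tree scales; clinical assessment protocol (CAP)
    trigger evaluation with stratified triggering rates; psychometric
    evaluation (Cronbach's alpha, weighted kappa, the c-statistic and
    banded-covariate convergent validity); risk-adjusted mental-health
    quality indicators via indirect standardization; per-diem case-mix
    index application and trend summaries; and a synthetic cohort
    generator with controlled reliability, diagnosis-association and
    longitudinal-improvement structure so the whole system is testable
    without proprietary clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
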