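Package: triagecea
Title: Cost-Effectiveness of a Urine-Biomarker Triage Test for Bladder
    Cancer Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Early cost-utility analysis of a urine-biomarker triage test
    used before flexible cystoscopy in the diagnostic work-up of
    haematuria patients suspected of bladder cancer. Couples a diagnostic
    decision tree (series triage rule) to a six-month-cycle Markov cohort
    model of bladder-cancer treatment with a delayed-detection track for
    false negatives, and computes discounted costs, QALYs and life years,
    ICER and net monetary benefit, deterministic sensitivity analyses
    (threshold price, prevalence, two-way price-by-prevalence, cystoscopy
    disutility), probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and regression-based expected
    value of (partial) perfect information.
License: MIT
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
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
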