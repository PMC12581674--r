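Package: akirank
Title: Hierarchical Global-Rank Composite Endpoints for AKI Prevention Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for randomized ICU trials that assess kidney
    protection with a hierarchical composite endpoint (death, then kidney
    replacement therapy, then baseline-adjusted mean change in serum
    creatinine), compared between arms with exact or moment-refined Wilcoxon
    rank-sum inference. Includes KDIGO acute kidney injury staging from serum
    creatinine and urine output, trial eligibility screening with a
    configurable AKI risk score, secondary and safety endpoints (ICU- and
    hospital-free days, new or progressive AKI, hypercalcemia and
    hyperphosphatemia flags, SOFA scoring), mixed-model longitudinal
    comparisons with multiple-imputation pooling by Rubin's rules, analytic
    and simulation-based power calculations for standardized effects, and a
    calibrated synthetic three-arm cohort generator (stratified permuted-block
    randomization, lognormal vitamin D metabolite kinetics, creatinine
    trajectories, events, and safety labs) so the full pipeline runs without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    nlme
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
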