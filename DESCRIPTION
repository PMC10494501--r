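Package: owncontrol
Title: Self-Controlled Effectiveness Analysis of Osteoporosis Medications
    from Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for own-control (self-controlled) effectiveness
    analyses of osteoporosis medications in longitudinal claims data:
    treatment-episode construction from dispensing claims with a new-user
    washout and a refill grace period, hierarchical cohort assignment,
    hospitalized fragility-fracture event identification with a 90-day
    same-site independence rule and overlapping site groups, period-wise
    person-time attribution under as-treated, intent-to-treat and
    virtual-exposure censoring, and incidence rate ratios with exact
    Poisson and exact conditional (binomial) confidence intervals. A
    synthetic claims generator with known piecewise-constant hazards makes
    every stage testable without access to restricted claims databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
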