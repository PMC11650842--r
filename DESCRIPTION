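Package: trialcea
Title: Within-Trial Cost-Effectiveness Analysis for Cluster-Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-trial economic evaluation of cluster-randomised
    health interventions in low-resource settings: costing of participant-level
    resource use against a unit-price schedule, EQ-5D-3L utility valuation and
    area-under-the-curve QALYs, identity-link GLM estimation of incremental
    costs and QALYs with modified Park test family selection, nonparametric
    bootstrap uncertainty, multiple imputation with Rubin pooling, incremental
    cost-effectiveness ratios, net monetary benefit, cost-effectiveness planes
    and acceptability curves, and sub-group/scenario sensitivity analyses.
    Includes a calibrated synthetic trial generator so the full pipeline can be
    exercised and validated without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
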