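Package: compsafety
Title: Comparative Drug-Safety Analysis from Spontaneous Reports and Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-track comparative-safety analysis pipeline for drug classes,
    developed around the comparison of DPP-4 inhibitors with metformin. Track
    one performs Bayesian Confidence Propagation Neural Network (BCPNN)
    disproportionality analysis on spontaneous adverse-event reports: case-level
    2x2 contingency tables for configurable drug classes and event groups,
    closed-form posterior moments of the information component (IC), and the
    IC025 > 0 signal criterion. Track two runs a new-user active-comparator
    cohort study on claims data: washout-based new-user identification,
    exclusion rules with attrition accounting, 1:1 nearest-neighbour propensity
    matching with a caliper of 0.2 standard deviations of the logit score,
    Kaplan-Meier cumulative incidence, and Cox proportional-hazards estimation
    with a fixed-margin non-inferiority decision. Synthetic generators for both
    report streams and claims populations with known reporting ratios, hazard
    ratios and confounding structure make every stage testable without access
    to proprietary databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
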