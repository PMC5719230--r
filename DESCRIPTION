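Package: stopgame
Title: Simulation and Analysis of Gamified Stop Signal Task Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal web-based Stop Signal Task (SST) studies
    with gamified variants. Provides a deterministic task engine (trial
    scheduling, four-staircase stop-signal-delay tracking, a points scoring
    state machine), a race-model cohort simulator with known ground truth
    (ex-Gaussian go processes, per-variant dropout hazards, visual-analog
    questionnaires, loss-of-focus counts), per-session stop signal reaction
    time (SSRT) estimation via inhibition-function fitting with race-model
    exclusion rules, engagement and attrition metrics, and an inferential
    layer: Kaplan-Meier/log-rank survival comparison, one-way and mixed
    ANOVAs with partial eta squared, post hoc t tests, Jeffreys-Zellner-Siow
    (JZS) Bayes factor t tests, logistic regression of next-day return, and
    noncentral chi-square power/sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
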