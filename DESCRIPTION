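Package: rowergetics
Title: Energy Cost of Ergometer Rowing from Incremental Exercise Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes the energy cost of ergometer rowing (ECR) from
    incremental-test data on air-braked rowing ergometers: power/pace/speed
    conversions under the cube-law drag model, open-circuit indirect
    calorimetry with Haldane transform and substrate-oxidation partitioning,
    a per-step ECR statistic combining oxygen uptake with a blood-lactate
    oxygen equivalent, lactate-threshold interpolation at 2 and 4 mmol/L by
    polynomial fitting, two-segment breakpoint detection of the ECR-vs-speed
    plateau, and cohort-level statistics (mixed-effects speed effect,
    Pearson correlations with false-discovery-rate adjustment). Includes a
    mechanistic generator of synthetic elite-rower cohorts so the full
    pipeline is testable without access to athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    nlme,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
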