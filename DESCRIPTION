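Package: erpmci
Title: Prefrontal Oddball ERP Difference-Wave Features and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for prefrontal selective-attention
    event-related potentials (ERPs) in a two-group elderly cohort (cognitively
    normal vs. mild cognitive impairment). Generates seeded auditory-oddball EEG
    sessions with injected N100/P300 components, measures the nine
    difference-wave features (peak amplitude and latency, zero-crossing onset and
    offset, 50% fractional-area latency, area under the curve and the derived
    intervals) together with six task-performance measures, and runs the group
    statistical battery: pooled-variance t-tests (from raw data or printed
    summaries), chi-squared tests, nested logistic regression models and
    covariate-adjusted Pearson partial correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
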