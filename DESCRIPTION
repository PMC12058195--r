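Package: dyncpm
Title: Dynamic Connectome-Based Predictive Modeling of Continuous Affect
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for predicting continuous emotional arousal
    from dynamic functional connectivity. Turns timestamped continuous
    rating logs into hemodynamically-lagged group targets, computes
    tapered sliding-window Fisher-z connectivity from ROI time series,
    trains connectome-based predictive models (radial-basis support
    vector regression with leave-one-subject-out cross-validation and
    across-dataset generalization), builds phase-randomized and
    resampling null distributions, and characterizes the anatomy of the
    selected edge sets (hypergeometric and Jaccard overlap tests,
    network-pair enrichment with permutation and FDR). Ships a synthetic
    data generator that plants a known arousal-coupled edge set so every
    stage is testable without neuroimaging downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
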