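Package: cureforest
Title: Cure-Fraction Random Survival Forests for High-Dimensional
    Time-to-Event Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Random survival forests for cohorts that mix susceptible and
    non-susceptible (cured) subjects, such as patients who may or may not
    ever develop anti-drug antibodies against a biotherapy.  Implements a
    bounded-cumulative-hazard (promotion-time) survival model with a
    mechanistic Poisson-clone simulator, a two-degree-of-freedom score
    statistic for node splitting that separates differences in the cured
    fraction from differences in event dynamics, survival trees with
    Nelson-Aalen leaf estimates, and forests built by bootstrap resampling
    combined with per-tree random feature-subspace sampling (alongside
    classical per-node mtry and bagging modes).  Includes out-of-bag
    evaluation via Harrell's concordance index, Hardy-Weinberg noise
    genotype generators for high-dimensional benchmarks, and drivers for
    subsampling-fraction sweeps and per-subject predicted risk curves.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
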