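Package: painscore
Title: Pain-Specific Behaviour Scoring and Discriminant Analysis for
    Post-Surgical Mouse Welfare Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing post-surgical pain in laboratory mice from
    ethogram data (per-animal behaviour frequencies and durations). Implements
    canonical discriminant analysis from the between/within scatter
    eigenproblem with sequential Wilks' lambda tests and structure
    correlations, loading-threshold selection of pain-specific versus normal
    behaviours, composite behaviour scores (Score 1, Score 2, the geometric
    activity summary G-behave), frequency banding of automated home-cage
    observations, and a factorial inference layer (Strain x Surgery x
    Treatment ANOVA with Bonferroni post-hocs, body-weight percent change,
    faecal corticosterone log change). Includes a calibrated synthetic-cohort
    generator for the vasectomy/buprenorphine study design so the full
    pipeline can be exercised without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
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
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
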