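Package: pitchspace
Title: Space Evaluation for Football Tracking Data via Arrival-Time Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluates space on a football pitch from player tracking data
    using per-location minimum arrival times under a damped-acceleration
    motion model. Provides the orthogonal safety (z1) and sparsity (z2)
    coordinates obtained by rotating the offense/defense arrival-time axes,
    a four-way field division into safe/risky and dense/sparse regions,
    formation centroid and spread summaries with the formation-relative
    pass distance, and pass-outcome statistics: class-conditional normal
    fits, empirical success curves, logistic (sigmoid) pass-success models
    and their Bayes closed form. Includes seeded synthetic-data generators
    for snapshots, tracks and pass datasets so the full pipeline is
    testable without proprietary tracking feeds, plus CSV readers/writers
    for simple tracking and pass-event schemas and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
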