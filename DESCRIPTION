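Package: spikecollide
Title: Collision-Aware Benchmarking of Spike Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained benchmark framework for studying how spike
    sorters resolve spike collisions. Simulates extracellular recordings on
    a multi-column hexagonal probe with parametric spatiotemporal templates,
    correlated Poisson spike trains (mixture-process construction) and
    additive Gaussian noise; compares sorting outputs against ground truth
    via agreement scores, Hungarian assignment, per-spike TP/FP/FN labels
    and unit classification; and computes collision-specific metrics,
    collision recall per lag bin and per template cosine similarity, and
    lag-wise relative errors of cross-correlograms. Ships reference sorters
    (oracle, configurable degraded oracle, greedy template matching) so the
    full pipeline runs without external sorters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
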