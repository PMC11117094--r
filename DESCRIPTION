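Package: tripartite
Title: Tripartite Information Decomposition with Noise-Robust Significance Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decomposes the relation between two source signals and a target
    signal into unique, redundant and synergistic components using four
    measures: partial correlation, variance partitioning on a quadratic
    interaction model, minimal-mutual-information partial information
    decomposition (discrete and continuous via a Kraskov nearest-neighbour
    estimator), and the BROJA unique-information decomposition solved as a
    convex program. Ships simulators for ground-truth triplet models and
    mixing/switching observation noise, permutation significance testing with
    target-only shuffles, and a conservative composite-null testing procedure
    that suppresses noise-induced false positives by maximising critical
    values over adversarial zero-atom models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
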