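Package: admixclock
Title: Dating Population Divergence and Admixture with Calibrated
    Coalescent Clocks and Ancestry Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating the origin and spread of admixed populations
    from genomic data. Calibrates the coalescent scaling factor (mutation
    rate and generation time) by maximizing the Bhattacharyya overlap
    between an inferred migration-rate trajectory and a historical event
    record; converts cross-coalescence output into relative
    cross-coalescence rates, effective population sizes and calendar time;
    infers diploid local ancestry at ancestry-informative sites with a
    single-pulse hidden Markov model, dates the admixture pulse by maximum
    likelihood with block-bootstrap confidence intervals, and calls
    ancestry tracts; computes f3 admixture statistics with block-jackknife
    standard errors and circular-chromosome permutation tests for shared
    ancestry hotspots; and runs tract-placement power simulations. A
    synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
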