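Package: coseg
Title: Co-Segregation and Co-Selection Dynamics of Extrachromosomal DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic modelling and inference of the joint inheritance of
    multiple extrachromosomal DNA (ecDNA) species in growing cancer cell
    populations. Provides division-level segregation rules (element-level
    coupling, cell-level extreme pairing, fraction-coupled splits), a
    continuous-time birth-death population simulator with presence-based
    selection, approximate Bayesian computation with sequential Monte Carlo
    (ABC-SMC) to infer selection, co-selection and co-segregation from
    single-cell summary statistics, multi-phase treatment scenario schedules,
    background-normalised single-cell copy-number calling with an
    ecDNA-signature classifier, daughter-cell co-segregation statistics with
    fusion-aware null models, and synthetic data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
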