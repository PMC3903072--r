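Package: mutclock
Title: Timing Tumor Evolution from Passenger Alteration Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the age of a tumor lineage (in cell divisions) and the
    timing of driver alterations from counts of passenger somatic alterations,
    and identifies mutator drivers that elevate the passenger alteration rate.
    Passenger point mutations or copy-number alterations are modelled as a
    Poisson process along the founder-cell lineage whose rate steps up when a
    mutator driver is altered; tumor age, per-driver alteration times and an
    exposure term are latent with truncated-Gamma, Gamma-plus-atom and
    exponential priors, and hyperparameters are estimated by maximum marginal
    likelihood. Includes preprocessing of segmented copy-number and mutation
    tables into passenger counts and driver indicators, a forward simulator of
    the full generative model, bootstrap confidence intervals, per-sample
    driver-order trees and reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
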