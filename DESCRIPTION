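Package: expandctrl
Title: Expanded Control Groups for Genome-Wide Association Studies with
    Multidimensional-Scaling Structure Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide association testing when the control
    group is expanded with external, possibly population-mismatched,
    reference samples. Computes pairwise identity-by-state (IBS) from a
    genotype dosage matrix, extracts axes of genetic variation by classical
    multidimensional scaling of 1-IBS distances, forward-selects the axes
    associated with disease, and adjusts logistic-regression trend tests
    for the selected axes. Includes a Balding-Nichols simulator of diverged
    cohorts under a multiplicative disease model, replicate-level drivers
    estimating false-positive error rate and power of the within-study,
    naive expanded-control and MDS-adjusted trend tests, and a closed-form
    power calculator for the one-degree-of-freedom trend test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
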