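Package: gliomrs
Title: Non-Invasive IDH Genotype Prediction from Single-Voxel 1H-MR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates labeled cohorts of in vivo single-voxel 1H magnetic
    resonance spectroscopy (MRS) spectra of IDH-mutant and IDH-wildtype
    gliomas, preprocesses them (zero-order phase correction, choline
    referencing and alignment, equidistant binning, region selection,
    total-intensity normalization, log2 transform), classifies them with a
    nested leave-one-out cross-validated linear support vector machine using
    t-test filter feature selection, and reports performance with exact
    Clopper-Pearson binomial confidence intervals, ROC/AUC, class-averaged
    spectra and metabolite-level feature annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
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
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
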