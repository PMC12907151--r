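Package: ramancell
Title: Label-Free Raman Spectral Phenotyping of Cell Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for single-cell Raman microspectroscopy in the
    biological fingerprint region (600-1800 1/cm): cosmic-ray despiking,
    rubber-band (lower convex hull) baseline correction, vector
    normalization, group mean and subtraction spectra, Savitzky-Golay
    negative-second-derivative band analysis with literature band
    assignment, and a leakage-controlled classification pipeline
    (train-only standardization, principal component reduction, and a
    small multilayer perceptron) for discriminating cell phenotypes such
    as a pediatric glioblastoma stem-cell line from adult lines. Includes
    a hierarchical synthetic-cohort simulator so the full pipeline can be
    exercised and validated without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
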