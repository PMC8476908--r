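Package: epidshift
Title: Detecting Patient Position Errors from EPID Transmission Fluence Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in-vivo dosimetry quality assurance in radiotherapy:
    simulate electronic portal imaging device (EPID) transmission fluence maps
    for volumetric modulated arc therapy deliveries with injected 3D couch
    shifts, quantify deviations between a baseline and a perturbed map with
    dose-difference and structural-similarity (SSIM) component maps, extract
    gray-level texture radiomics from the comparison maps, and classify the
    injected shift (presence, per-axis, and 8-way combined) with classical
    machine-learning models and a four-branch convolutional network. Includes
    evaluation utilities (ROC/AUC, confusion matrices, per-class metrics),
    TIFF/DICOM map readers, cohort manifests, and a single-call study
    replication driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    class,
    e1071,
    xgboost,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
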