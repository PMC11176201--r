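Package: wallradiomics
Title: Radiomic Analysis of the Urinary Bladder Wall from MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for hollow-organ (bladder wall) radiomics from
    3D MR volumes and co-registered wall masks: histogram-landmark intensity
    standardization, multi-family feature extraction (morphological,
    intensity, gray-level co-occurrence texture, clinical), hybrid
    filter/wrapper feature selection scored by cross-validated
    classification, and repeated stratified K-fold evaluation of low versus
    moderate-to-severe IPSS classifiers. Includes a synthetic phantom-cohort
    generator so every stage is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    e1071,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
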