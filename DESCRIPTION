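Package: ctDoseSens
Title: Sensitivity of Radiotherapy Isocentre Dose to Hounsfield-Unit Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how localized Hounsfield-unit (HU) errors in CT or
    synthetic-CT images propagate to the photon dose at the treatment
    isocentre of a prostate plan. Provides a parametric synthetic pelvic
    phantom cohort (body, bone, bladder, rectum, prostate), controlled HU
    error injection (spherical artefacts and organ-wise mean shifts), a
    simplified seven-beam 6 MV dose model based on water-equivalent path
    length ray tracing, Spearman rank-correlation sweeps, and Morris
    elementary-effects global sensitivity analysis with mu/mu-star/sigma
    summaries and Euclidean-distance factor ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    rlang,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
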