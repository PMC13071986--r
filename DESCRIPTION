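Package: ctbone
Title: Micro-CT Bone Morphometry for Longitudinal Fixation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative micro-CT bone morphometry for longitudinal studies
    of whole long bones, built around attenuation volumes reconstructed in
    physical units (mm^-1). Provides Otsu threshold segmentation with a
    single threshold shared across a scan series, morphological separation
    of cortical and trabecular compartments, delineation of the proximal
    epiphysis/metaphysis zone, diaphysis and distal epiphysis/metaphysis
    zone from the cross-sectional area profile, voxel-counting morphometry
    (TV, BV, Ct.BV, Tb.BV, BV/TV) with median linear attenuation
    coefficients, and baseline-relative percent-change analysis of a time
    series. A synthetic long-bone phantom generator with a parametric
    fixative drift model (formalin-like swelling and demineralization,
    ethanol-like stability) supplies ground truth for validating every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
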