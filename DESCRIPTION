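Package: regqa
Title: Positioning-Uncertainty Characterization for Multimodal Radiotherapy Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-assurance pipeline for quantifying patient-positioning
    uncertainty in combined CT-MRI radiotherapy imaging workflows. Provides
    rigid-body transform algebra with Euler-angle (pitch/roll/yaw)
    decomposition of registration matrices, a mutual-information rigid
    registration engine with a multi-resolution pyramid, a known-transform
    accuracy-validation protocol, a digital skull-phantom and patient-cohort
    shift simulator, and the descriptive, Bland-Altman, one-sample t-test and
    quadrature total-error statistics used to combine registration error with
    setup positioning error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
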