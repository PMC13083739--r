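Package: petmoco
Title: Evaluation of Data-Driven Head-Motion Correction in Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the impact of rigid head motion and of frame-based
    motion correction on dynamic brain positron emission tomography (PET).
    Provides a procedural brain phantom with regional labels and Poisson
    counting noise, rigid-body transform algebra and volumetric resampling,
    a frame-to-reference motion estimator based on normalized
    cross-correlation, image-space motion correction, probe-point motion
    summarisation with automatic motion categorization and cumulative
    displacement-time histograms, masked normalized cross-correlation over
    time, and region-of-interest relative signal differences with exact
    Mann-Whitney U comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
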