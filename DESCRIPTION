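Package: polypclip
Title: Spatio-Temporal Optical Diagnosis of Colorectal Polyps from Video Clips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clip-level adenoma versus non-adenoma classification of
    colorectal polyps in colonoscopy video. Provides a frame-level
    convolutional classifier and a long-term recurrent convolutional network
    (CNN encoder followed by an LSTM with a many-to-one readout) trained from
    scratch in R, temporal aggregation of per-frame probabilities (soft
    averaging, plurality vote, extreme vote, cross-fold ensembling),
    per-lesion accuracy metrics with confidence intervals, normalised
    cross-correlation clip-similarity analysis, a detection-conditioned
    classification pipeline with a simulated detector, bounding-box IoU
    perturbation robustness protocols, patient-level cross-validation
    splitting, and a procedural generator of labelled polyp-like video
    datasets and prediction streams for fully synthetic end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
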