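Package: swsal
Title: Semi-Weakly Supervised Segmentation and Active-Learning Annotation for MRI Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic annotation of volumetric (slice-stack) MRI segmentation
    datasets from very few dense labels. Trains a small dual-head (segmentation +
    edge) convolutional network in three stages: sparse segmentation labels with an
    edge-aware loss, pseudo-labels grown from bounding boxes by seeded region
    growing with iterative self-refinement, and scheduled joint training that
    shifts weight from pseudo- to true labels. An active-learning annotation loop
    then selects the slices whose predictions disagree most with their neighbours
    (adjacent-slice Dice), has a simulated annotator correct them, and retrains,
    while accounting workload in equivalent segmentation slices. Includes a
    synthetic two-tissue phantom generator (compact bone-like and thin
    cartilage-like structures with smooth inter-slice drift) so the whole pipeline
    runs without any external dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
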