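Package: vbdetect
Title: Small-Object Detection of Vascular Bundles in Stem Cross-Section Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CPU detector for small, densely packed vascular bundles in plant
    stem cross-section micrographs. Implements dynamic snake convolution blocks
    with vector-quantized kernels and fitted distribution shifts, a multi-scale
    feature-fusion neck with an extra stride-4 detection head, and the PIoU
    bounding-box regression loss alongside the CIoU baseline. Ships a full
    detection evaluation suite (precision, recall, AP/mAP over IoU thresholds,
    MAPE/RMSE on counts and areas, Dice and region IoU), LabelMe/YOLO annotation
    I/O, a synthetic stem cross-section generator with exact ground truth, and a
    training/evaluation/detection harness with a command-line interface. The
    network runs on a small reverse-mode automatic-differentiation engine with
    compiled convolution kernels, so training and inference need only a CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    tiff,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
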