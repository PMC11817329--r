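Package: wbfusion
Title: Weighted Boxes Fusion and Bayesian-Optimized Detector Ensembling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble post-processing for object detectors. Merges bounding-box
    predictions from two or more detection models with Weighted Boxes Fusion
    (confidence-weighted coordinate averaging over IoU clusters), tunes the
    fusion hyperparameters (IoU threshold, skip-box threshold, per-model
    weights) by Gaussian-process Bayesian optimization with the Expected
    Improvement acquisition, and scores results with the standard detection
    metrics: greedy IoU >= 0.5 matching, precision, recall, F1, average
    precision and mAP@0.5. Reads and writes YOLO-format label files and
    COCO-style detection-results JSON, performs reproducible train/val/test
    splits, and ships a synthetic two-detector benchmark generator (missed
    detections, Poisson false positives, Gaussian localization jitter,
    IoU-linked confidences) so the whole pipeline runs without images or GPUs.
    Motivated by ensembling real-time detectors on dental panoramic
    radiographs, but agnostic to the detection task.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
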