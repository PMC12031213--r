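Package: medgest
Title: Medication-Taking Gesture Detection from Wrist-Worn Accelerometers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and classification pipeline for detecting
    medication-taking gestures (oral liquid methadone and sublingual
    buprenorphine film) in 100 Hz tri-axial smartwatch accelerometer
    streams. Provides a protocol-faithful synthetic cohort generator with
    ground-truth bout annotations, shake-marker gesture segmentation,
    fixed-length 4-second windowing with retention accounting,
    leakage-controlled train/validation/test splitting at gesture,
    recording, or participant level, a RegNet-style 1D residual
    convolutional network trained with AdamW and early stopping, and
    confusion-matrix metrics (precision, recall, macro F1), precision-recall
    curves and t-SNE embedding projections across three evaluation
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
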