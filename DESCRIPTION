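Package: tmjjsw
Title: Joint Space Width Measurement and Segmentation Evaluation for
    Temporomandibular Joint Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated ultrasonographic assessment of the
    temporomandibular joint (TMJ) from multi-class segmentation masks
    (mandibular condyle, joint space, glenoid fossa). Provides
    connected-component filtering of predicted masks, a joint-space-width
    (JSW) measurement algorithm based on the superior-most condyle point
    and its vertically aligned fossa point, per-class segmentation metrics
    (Dice, precision, recall, volume similarity, Hausdorff distance),
    Bland-Altman style method-agreement statistics, a seeded synthetic
    speckle-phantom generator with known ground-truth JSW, and a compact
    2D residual U-Net training and ensembling harness for CPU-scale
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    Matrix,
    igraph,
    withr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma
Config/testthat/edition: 3
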