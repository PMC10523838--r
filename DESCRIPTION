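Package: somaswin
Title: Shifted-Window Transformer Segmentation of Fluorescent Neuronal
    Somas in Multiphoton Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automated 2D detection and segmentation of fluorescently
    labeled neuronal cell bodies (somas) in thick-slice two-photon
    images. Provides copy-paste-blend synthetic training image
    generation from annotated cells and background tiles, maximum
    intensity projection preprocessing (background subtraction, median
    smoothing, CLAHE), a from-scratch hierarchical shifted-window
    (Swin) transformer backbone, a trainable per-pixel instance head
    with confidence thresholding, and a quantitative evaluation
    protocol (Dice, IoU, instance matching, precision, recall, yield
    rate, somatic area agreement, threshold sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    matrixStats,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
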