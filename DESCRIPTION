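Package: tumortexture
Title: Composite GLCM/LBP Texture Features and Linear-SVM Evaluation for
    Tumor Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts a fixed-length composite texture descriptor from 2-D
    grayscale images: five gray-level co-occurrence matrix (GLCM) statistics
    averaged over four angles, a 256-bin local binary pattern (LBP)
    histogram, their outer-product interaction features, and aggregated,
    statistical and log-transform summaries of the GLCM vector, concatenated
    into a 1547-dimensional vector per image. Includes a linear-kernel
    support vector machine training and evaluation harness with a full
    confusion-matrix metric battery (accuracy, precision, recall, F1,
    sensitivity, specificity, TPR/FPR/FNR/TNR, per-class Dice), one-vs-rest
    ROC curves with micro-average AUC, and learning curves, together with a
    reproducible synthetic texture-image generator so the whole pipeline can
    be exercised without external data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    e1071,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
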