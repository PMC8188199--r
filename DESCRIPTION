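Package: deepclass
Title: Headless Deep-Learning Image Classification for Microscopy and
    Imaging Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable workbench for training convolutional and
    multilayer-perceptron classifiers on labeled biological image
    collections: uniform dataset containers with HDF5 and image-folder
    readers, luminosity color conversion, scaling/cropping/padding and
    normalization, a stochastic augmentation engine with reproducible
    seeding, balanced per-epoch class sampling, class-weighted training
    with live hyper-parameter updates and automatic provenance meta-files,
    transfer learning with per-layer freezing and plateau-triggered
    unfreezing, full evaluation reports (confusion matrix, precision,
    recall, F1, ROC and precision-recall curves, probability-threshold
    purity), a tile-based segmentation-as-classification pipeline for
    stained-culture micrographs, and synthetic fixture generators for
    shapes, stained cultures, and cell-event populations. The neural
    network engine (im2col convolution, pooling, dense layers, dropout,
    softmax cross-entropy with class weights, SGD with momentum) is
    implemented in vectorized R with no external deep-learning runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    rhdf5,
    yaml,
    digest,
    jsonlite,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
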