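Package: buscad
Title: Breast-Ultrasound Lesion Segmentation, Handcrafted Features, and
    SVM Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computer-aided analysis of 2D breast-ultrasound (BUS) images.
    Segments a lesion with distance-regularized level-set evolution (DRLSE),
    computes four handcrafted characteristic features (height/width
    orientation, edge-indistinctness score, Hu-moment posterior-shadow
    score, and fractal shape-complexity slope from the divider method),
    normalizes features by min-max scaling, optionally fuses them serially
    with precomputed deep-feature vectors, and classifies lesions with an
    RBF-kernel support vector machine tuned by stratified 3-fold
    grid-search cross-validation.  A seeded synthetic speckle-phantom
    generator makes every stage testable without clinical data, and a
    command-line interface exposes the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    e1071,
    pROC,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
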