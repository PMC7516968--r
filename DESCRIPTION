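Package: lesionfuse
Title: Melanoma-Nevus Classification by Fusing Handcrafted and Deep
    Dermoscopy Features with Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A computer-aided detection pipeline for pigmented skin
    lesions in dermoscopy images. Segments the lesion by CIELab mean
    thresholding, extracts a 43-element handcrafted feature vector
    (bilateral asymmetry, moment-ellipse shape descriptors, per-channel
    color statistics, and Haralick gray-level co-occurrence texture),
    appends deep features through a pluggable extractor contract,
    fuses the two blocks by ranking per-feature mutual information with
    the class label (Ross k-nearest-neighbor estimator) against the
    mean-MI threshold, balances training data with SMOTE, and trains
    shallow classifiers evaluated with imbalance-aware metrics
    (G-mean, dominance, index of balanced accuracy, Matthews
    correlation). Ships a synthetic lesion-image and feature-table
    generator with ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    e1071,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    kernlab,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
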