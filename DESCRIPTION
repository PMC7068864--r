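Package: lesionclass
Title: Dermoscopy Lesion Classification with Hand-Crafted Features, a
    VGG16-Style Network, and Case-Based Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for classifying dermoscopy skin-lesion
    images as benign or malignant. Provides a seeded generator of synthetic
    lesion images with ground-truth masks; point-of-interest seeded
    region-growing segmentation with the associated preprocessing chain
    (gray conversion, 3x3 zero-padded median filter, contrast stretching,
    morphological refinement); a twelve-dimensional colour/shape descriptor
    (mean RGB/HSV, colour-structure entropy, colour-layout DCT coefficients,
    principal-component ratio, fitted-ellipse coverage); k-nearest-neighbour
    and support-vector-machine classifiers over the descriptor; reference
    implementations of the convolution, pooling, activation, softmax and
    multinomial-logistic-loss operators together with a declarative builder
    and trainer for a sixteen-layer VGG16-style convolutional network;
    a threshold-sweep ROC/PR evaluation suite over confusion counts; and a
    case-based-reasoning layer that retrieves the nearest stored cases for
    a query image by embedding distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    rhdf5,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
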