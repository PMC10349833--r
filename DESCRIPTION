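Package: dermsp
Title: Superpixel-Based Geometric Features for Skin Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying dermoscopy skin lesions
    (melanoma versus nevus) at the superpixel level. Images are cleaned of hair
    artifacts by morphological closing with linear structuring elements
    (Dull Razor), the lesion region of interest is extracted by a seeded
    min-cut (graph cut) segmentation, superpixels are generated by SLIC and
    background superpixels are eliminated against the lesion mask (iSLIC),
    six geometric descriptors (area, perimeter, eccentricity, orientation,
    convex area, major axis length) are computed per superpixel from image
    moments, and nine classifiers (random forest, linear SVM, AdaBoost,
    1-nearest-neighbour, decision tree, Gaussian naive Bayes, and three small
    neural networks) are trained on z-score-normalized feature tables and
    scored by confusion-matrix metrics including the Matthews correlation
    coefficient. A synthetic dermoscopy-image generator with ground-truth
    masks makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    png,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
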