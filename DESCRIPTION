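Package: rootgrader
Title: Machine-Vision Grading of Panax notoginseng Taproots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-based grading pipeline for Panax notoginseng taproots.
    Generates grade-labelled synthetic root images, segments specimens by
    Gaussian filtering, Otsu thresholding and morphological cleaning, extracts
    a fused 40-dimensional feature vector (nine shape and size descriptors,
    twenty-four RGB/HSV color moments, seven gray-level co-occurrence matrix
    texture statistics), reduces it with IRIV, VISSA or stepwise regression
    scored by cross-validated RMSE, and classifies grades with an RBF support
    vector machine whose penalty and kernel width are tuned by grey wolf,
    genetic or particle-swarm optimisation. Extreme learning machine and
    backpropagation network baselines are included, as are broom-style tidiers
    and ggplot2 plotting methods for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
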