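Package: marrowdx
Title: Contextual Segmentation and Classification of Leukocytes in Bone Marrow Smears
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contextual analysis of stained bone-marrow smear images for acute
    leukemia screening. Implements CIE L*a*b* colour modelling with k-means
    channel grouping, 2-D Wold texture decomposition (harmonic, generalized
    evanescent and stochastic fields), binary Markov-random-field segmentation
    of leukocyte nuclei and whole cells solved by iterated conditional modes,
    rule-based identification of nuclei, cells and overlapped aggregates,
    separation of overlapped cells by concave-point cuts closed with linear
    interpolation in polar coordinates, a 67-descriptor morphometric/GLCM/eigen
    feature panel, cross-validated classification of leukemia families and FAB
    subtypes, and per-patient majority-vote diagnosis with cascade and
    classifier-fusion schemes. Ships a synthetic Wright-stain smear generator
    with ground-truth masks so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    grDevices,
    randomForest,
    e1071,
    nnet,
    rpart,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
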