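Package: frailmotion
Title: Frailty Phenotype Classification from Depth-Camera Skeleton Motion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for classifying the Fried frailty phenotype (healthy
    versus pre-frail) and gender from 25-joint depth-camera skeleton time
    series recorded during four functional exercises (30-s arm curl, 30-s
    chair sit-to-stand, 4-m gait and 2-min step). Provides Gaussian
    smoothing of joint trajectories, automatic multiscale peak detection
    (AMPD) for movement-cycle segmentation, four geometric feature families
    (spherical limb angles, inter-joint distances, joint cosine
    dissimilarity and joint triangular area relative to the spine), bin-mean
    and histogram aggregation into fixed-length feature vectors, standard
    scaling, random-forest Gini-importance feature selection, and five
    classifiers (k-nearest neighbours, support vector, multi-layer
    perceptron, bagged trees and soft voting) tuned by randomized-search
    k-fold cross-validation with subject-disjoint holdout evaluation. A
    synthetic-motion generator with analytic ground truth supports testing
    every stage without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    randomForest,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
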