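Package: neurodc
Title: Voxel-Wise Degree Centrality Mapping and Machine-Learning
    Classification for Resting-State fMRI
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes voxel-level degree-centrality (DC) maps from masked 4D
    resting-state BOLD series (thresholded Pearson correlation graph, z
    transformation, Gaussian smoothing), extracts atlas region-mean zDC
    features, performs two-stage feature selection (pairwise absolute
    correlation pruning followed by L1-penalized logistic regression over a
    log-spaced alpha grid with cross-validated mean-squared-error scoring),
    and evaluates linear SVM, random forest and logistic regression
    classifiers under leave-one-out cross-validation with pooled-score
    ROC/AUC, Cohen's kappa and permutation testing. Includes a synthetic
    cohort generator that plants known degree differences between two
    groups, and closed-form demographic group comparisons from printed
    summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    nortest,
    withr
Config/testthat/edition: 3
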