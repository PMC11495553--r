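Package: rsbagging
Title: EEG Connectivity, Microstates, and Undersampling-Bagged SVM Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Feature extraction and classification tools for resting-state
    EEG in clinical cohorts. Computes eleven functional and effective
    connectivity measures (coherence, phase-locking value, phase-lag index
    family, pairwise phase consistency, cross-spectral density,
    orthogonalized power correlation, and MVAR-based Granger causality,
    directed transfer function and partial directed coherence), performs
    polarity-invariant microstate segmentation with statistical parameter
    extraction, and classifies imbalanced cohorts with RSBagging: a bagging
    ensemble of Gaussian-kernel support vector machines trained on balanced
    random-undersampled subsets and fused by an abstaining soft vote with
    threshold alpha, evaluated with accuracy, sensitivity, specificity,
    F1-score and Predict Rate. Includes seeded synthetic generators for
    coupled oscillators, multivariate autoregressive systems, microstate
    sequences and imbalanced clinical cohorts so every stage is testable
    without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
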