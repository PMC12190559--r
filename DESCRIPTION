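Package: hfsa
Title: Hybrid Filter-Wrapper Feature Selection for Symptom-Based Disease Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A three-layer diagnostic system for binary symptom-disease tables:
    a genetic-algorithm rejection layer that evolves an inlier mask over
    training cases, a selection layer combining a chi-square filter (fast
    stage) with a hybrid binary genetic algorithm / Tiki-Taka metaheuristic
    wrapper (accurate stage) whose fitness is cross-validated naive-Bayes
    accuracy, and a Bernoulli naive-Bayes diagnostic layer. Includes a
    synthetic symptom-disease data generator with planted informative
    features and outliers, a k-nearest-neighbour baseline, confusion-matrix
    and macro ROC-AUC metrics, stratified k-fold cross-validation, and a
    command-line pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
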