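Package: sgclass
Title: Single-Gene Classifiers for Two-Class Gene Expression Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trains and evaluates single-gene classifiers for two-class gene
    expression data. The most univariately discriminative gene is chosen by
    the two-sample t-test or the Wilcoxon-Mann-Whitney test, a single
    expression cut point is placed by minimising the class information
    entropy of the induced sample partition, and the decision direction is
    set by majority correctness on the training samples. Evaluation uses
    complete leave-one-out cross-validation in which gene selection and
    cut-point estimation are repeated in every fold, plus stratified
    split-sample validation, gene-selection stability reports and dataset
    difficulty characterisation. Standard comparators (diagonal linear
    discriminant analysis, k-nearest neighbours, linear support vector
    machine, random forest, top-scoring pair) run behind the same
    train/predict interface, and a seeded synthetic-data generator provides
    two-class Gaussian expression data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite, e1071, randomForest
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
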