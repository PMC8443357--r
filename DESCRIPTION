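Package: gasvm
Title: Hybrid Genetic Algorithm and Support Vector Machine Classification
    for Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Wrapper feature selection for two-class transcriptomic
    classification.  A genetic algorithm jointly optimizes the
    hyperparameters (C, gamma) of a radial-basis-function support vector
    machine and a binary probe mask, using 10-fold cross-validated
    accuracy as the fitness function.  Includes a differential-expression
    pre-screen (per-probe Welch t test, Benjamini-Hochberg adjustment,
    fold-change filter), a synthetic two-class microarray simulator with
    planted differential probes, held-out evaluation by accuracy and the
    area under the ROC curve, and a pipeline that compares the plain SVM
    against the hybrid GA-SVM with and without pre-screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
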