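Package: fallrisk
Title: Predicting Inpatient Falls from Free-Text Nursing Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case-control pipeline for predicting inpatient falls from
    free-text nursing records. Daily notes are embedded with jointly trained
    skip-gram negative-sampling word vectors and distributed bag-of-words
    paragraph vectors, multiplied into an interpretable document-word matrix,
    and classified with a Bayesian logistic regression fitted by Hamiltonian
    Monte Carlo under a normal prior, with SMOTE class balancing. A
    bisection ensemble of six primary models selects the stable risk
    vocabulary used by the final model. Evaluation follows the case-control
    design: per-patient risk scores, ROC analysis with the closest-to-(0,1)
    operating point, and sensitivity, specificity and odds ratios with
    confidence intervals. A seeded synthetic corpus generator with planted
    risk vocabulary and imminent-precursor windows provides a fully
    reproducible test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
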