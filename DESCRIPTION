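Package: swarmdx
Title: Swarm-Optimized Disease Classification with a Tamper-Evident Audit Trail
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for binary disease-risk classification on
    tabular clinical data: Z-score standardization, wrapper feature selection
    driven by a spotted hyena optimizer with an adaptive stopping rule, an
    attention bidirectional GRU classifier trained by mini-batch gradient
    descent, hyperparameter tuning by a coati optimizer modified with dynamic
    opposite learning, macro-averaged confusion-matrix reporting (accuracy,
    precision, recall, F-measure, MCC, Cohen's kappa), and a hash-chained
    audit ledger that makes any retroactive edit of committed inputs or
    reports detectable. A synthetic-data generator emulates the shape of the
    classic 303-patient heart-disease table so every stage is testable
    offline with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
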