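Package: acpep
Title: Anticancer Peptide Prediction from Hybrid Sequence Compositions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts anticancer peptides (ACPs) from primary sequence using a
    support vector machine over hybrid composition features: amino acid
    composition (AAC), dipeptide composition on a six-letter hydropathy-reduced
    alphabet (RAAC), and lagged auto-covariance of per-residue average NMR
    chemical shifts (acACS). Includes FASTA input/output with validation, an
    RBF-kernel SVM trained by sequential minimal optimization with grid-searched
    hyperparameters, jackknife and stratified k-fold cross-validation reporting
    sensitivity, specificity, overall accuracy and the Matthews correlation
    coefficient, a two-class peptide simulator with controllable compositional
    divergence, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
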