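Package: dcmpanel
Title: Stability-Oriented Gene Panel Discovery for Small-Cohort RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers disease-discriminating gene panels from small-cohort
    bulk RNA-seq count tables, motivated by dilated cardiomyopathy (DCM)
    versus healthy myocardium comparisons. Combines classic differential
    expression (Welch t on log2 CPM, Benjamini-Hochberg FDR) with a
    machine-learning workflow: a k-means / fold-change / cross-fold
    frequency feature-selection cascade executed inside leave-one-out
    cross-validation, and decision-tree induction with a
    stability-oriented splitting criterion plus a census of tree
    equality and specialization classes across folds. Includes Spearman
    association of panel genes with clinical covariates (exact small-n
    permutation p-values), hypergeometric over-representation against
    user-supplied gene sets, score-thresholded protein-interaction
    subnetwork extraction, and a negative-binomial count simulator with
    planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
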