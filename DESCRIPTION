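Package: dabnet
Title: Reconstruction of Directed Acyclic Boolean Networks by Two-Step
    Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs directed acyclic Boolean (DAB) gene networks from
    noisy binary on/off expression data.  For every gene pair the six
    pairwise relationships (two similarity patterns and four prerequisite
    patterns) are scored in two steps: counting numbers screened against
    misclassification-aware confidence-bound thresholds, and asymptotic
    p-values for the relationship hypotheses under an independent per-entry
    bit-flip error model.  Includes misclassification-corrected cell
    probability estimators, maximum-likelihood estimation of the flip rate,
    transitive closure and covering-pair reduction of the inferred network,
    a compatible-state simulator for benchmarking, and two comparison
    baselines (Boolean-implication sparseness statistics and a constrained
    error-rate criterion).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
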