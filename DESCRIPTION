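Package: actstate
Title: Bayesian Classification of Microbial Gene Activity States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies each gene in each experiment of a microbial expression
    compendium as active or inactive. Posterior activity probabilities are
    estimated with two-component Gaussian mixture models fitted by Gibbs
    sampling, either gene-by-gene (UniMM) or operon-by-operon with a shared
    activity state for all genes of an operon (MultiMM). Includes BIC-based
    screening of genes that never change state, a similarity-based multiple
    imputation fallback for such genes, threshold and rank baselines, a
    ground-truth compendium simulator, evaluation statistics (squared
    deviation, consistency, confidence strata, operon consistency), and rule
    engines mapping between gene-level activities and reaction-level
    predictions through gene-protein-reaction associations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
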