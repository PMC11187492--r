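Package: ehrseqrep
Title: Unsupervised Patient Representations from Disease-Code Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns and compares unsupervised patient representations from
    time-ordered sequences of clinical diagnosis codes, and evaluates their
    predictive content for one-year clinical outcomes. Provides a seeded
    synthetic primary-care cohort simulator (multimorbid patients, recurrent
    coding, sequence-order outcome effects), dual-vocabulary sequence
    construction (fine-grained codes and clinician-curated disease
    categories), baseline bag-of-words representations, latent Dirichlet
    allocation with perplexity-driven topic-number selection, paragraph-vector
    (doc2vec) embeddings with an identical-sequence selection criterion, a
    configurable BERT-style encoder family pretrained with masked language
    modelling, and a fixed cross-validated logistic evaluation harness
    reporting ROC-AUC, average precision and threshold metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    glmnet,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
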