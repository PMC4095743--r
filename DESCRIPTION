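Package: ppistrength
Title: Predicting Protein-Protein Interaction Strength from Domain Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts real-valued strengths of protein-protein interactions
    from protein domain information. Implements association-style estimators
    of domain-domain interaction probabilities (ASSOC, ASNM, APM) with the
    probabilistic noisy-OR combiner, domain-count (DN) and domain-restricted
    spectrum (SPD) feature mappings, Laplacian-kernel support vector
    regression and a sparse Bayesian relevance vector machine, and a nested
    cross-validation protocol with RMSE evaluation and coverage filtering.
    A synthetic-data generator with planted domain-interaction structure
    supports benchmarking without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    kernlab,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
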