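Package: tadard
Title: Gene Discovery from Inferred De Novo Variants with the Random Draw Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for rare-variant gene association when parental genotypes
    are missing. Implements ClassDn, an imbalanced-data classifier (RUSBoost
    and UnderBagging over undersampled decision trees) that scores rare
    protein-truncating variants in case-only samples for de novo status; the
    Random Draw model, a misclassification-aware Bayesian gene test that
    converts thresholded de novo scores into per-gene Bayes factors; the
    Poisson-Gamma de novo Bayes factor for family (trio) data; Bayesian FDR
    q-values and gene selection; and null (per-family error rate) and power
    simulations under a Gaussian de novo score model. A synthetic-data module
    generates labeled family-style and unlabeled case-only variant tables so
    the full pipeline can be exercised without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
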