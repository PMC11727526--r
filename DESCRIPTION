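Package: ssexp
Title: Expression-Integrated Single-Step BLUP for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for genomic prediction with multi-omics relationship
    matrices. Builds pedigree (A), genomic additive (G), genomic dominance (D)
    and transcriptomic (E) relationship matrices, combines limited-coverage
    layers with full-coverage ones through the single-step H matrix (with
    scale adjustment and a weighting factor w), fits additive + dominance
    linear mixed models by average-information REML, and evaluates prediction
    accuracy by replicated k-fold cross-validation over a sweep of w. Includes
    a negative-allowed Box-Cox phenotype transformation and a simulator for
    F2-like populations (pedigree, gene-dropped genotypes, genotype-coupled
    expression, phenotypes with known variance components) so the whole
    pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
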