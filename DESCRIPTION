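Package: dgvacc
Title: Accuracy of Direct Genomic Breeding Values by Relatedness-Clustered
    Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the accuracy of direct genomic breeding values (DGV)
    for nationally evaluated beef cattle traits. Implements weighted BayesC
    whole-genome regression on deregressed estimated breeding values, K-means
    cross-validation groups built from the pedigree numerator relationship
    matrix, a weighted bivariate animal-model REML for the trait-DGV genetic
    correlation and the heritability of DGV, and the efficiency of selection
    on DGV relative to parent average. Ships a synthetic-herd simulator
    (multi-generation pedigree, gene-dropped SNP genotypes, traits with known
    architecture, emulated national-evaluation output) so the whole pipeline
    is testable against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
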