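Package: micromut
Title: Joint Analysis of Tumor Mutational Profiles and the Tumor-Adjacent Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating somatic mutational profiles of tumors to the
    composition of the tumor-adjacent microbiome. Implements a two-stage
    discriminant-taxon screen (per-taxon Kruskal-Wallis test followed by
    bootstrapped linear discriminant analysis effect sizes), an unweighted
    arcsine-square-root risk-index classifier evaluated by leave-one-out
    cross-validation, Mann-Whitney U and label-permutation significance testing
    with false discovery rate correction, ROC/AUC assessment via stratified
    k-fold cross-validation, fixed-specificity and leave-one-out-refined
    risk-index cutoffs, SparCC compositional correlation networks conditioned
    on mutation status, covariate-adjusted per-taxon linear-model robustness
    checks, and a Dirichlet-multinomial generator of synthetic abundance tables
    with planted taxon-mutation associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
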