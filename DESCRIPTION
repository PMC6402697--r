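Package: mmctm
Title: Multi-Modal Correlated Topic Models for Mutation Signature Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Joint inference of single-nucleotide variant (SNV) and structural
    variant (SV) mutation signatures from cancer genomes using probabilistic
    topic models. Implements latent Dirichlet allocation (LDA), the correlated
    topic model (CTM) and a multi-modal correlated topic model (MMCTM) fitted
    by mean-field variational EM, together with independent-feature variants,
    feature encoders for trinucleotide SNV contexts and rearrangement
    categories, held-out predictive log-likelihood benchmarking, Poisson
    count simulation with signature-recovery scoring, and signature-based
    patient stratification (Ward clustering, enrichment tests, blocked
    permutation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    SummarizedExperiment,
    VariantAnnotation,
    glmnet
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    mclust,
    knitr
Config/testthat/edition: 3
biocViews: SomaticMutation, StatisticalMethod, Bayesian, Clustering
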