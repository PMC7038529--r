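Package: gpbench
Title: Simulation-Based Benchmarking of Genomic Prediction Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates complex traits on biallelic SNP genotypes under
    additive, dominance and two-locus epistatic gene action, and benchmarks
    parametric genomic predictors (GBLUP, Bayes B) against machine-learning
    regressors (random forest, gradient boosting, multilayer perceptron,
    convolutional neural network) under replicated five-fold cross-validation.
    Includes a synthetic genotype generator with linkage-disequilibrium
    blocks, PLINK/VCF/TSV genotype input and output, marker quality control
    (minor allele frequency, missingness, exact Hardy-Weinberg test), a
    genomic relationship matrix and mixed-model solver, a mixture-prior
    Gibbs sampler for marker effects, and tidy metric tables with summary
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    ranger,
    xgboost,
    vcfR,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'gpbench-package.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'genotype-sim.R'
    'genotype-qc.R'
    'genotype-io.R'
    'trait-qtn.R'
    'trait-effects.R'
    'trait-phenotype.R'
    'grm.R'
    'gblup.R'
    'bayesb.R'
    'ml-trees.R'
    'ml-nnet.R'
    'tuning.R'
    'evaluation.R'
    'pipeline.R'
    'RcppExports.R'
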