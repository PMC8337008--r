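Package: SpliceChain
Title: Splice Site Usage Estimation from RNA-seq with an Inhomogeneous
    Markov Chain
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the usage of exon start sites (3' acceptor splice
    sites and transcription start sites) and exon end sites (5' donor
    splice sites and transcription end sites) of a gene from RNA-seq
    data. A gene is partitioned into segments bounded by splice sites,
    TSS and TES; aligned reads are reduced to segment mapping signature
    counts, the sufficient statistics of the model; an inhomogeneous
    binary Markov chain over segment inclusion states models transcript
    structure, and site usage parameters are estimated by an EM
    algorithm with dynamic programming over segments and read start
    positions. Estimator uncertainty is quantified by multinomial
    bootstrap confidence intervals. The package includes a generative
    read simulator, a brute-force enumeration oracle for small genes,
    and evaluation utilities based on per-site Bernoulli
    Kullback-Leibler divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: AlternativeSplicing, RNASeq, Transcriptomics, StatisticalMethod
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'SpliceChain-package.R'
    'bootstrap.R'
    'chain.R'
    'em.R'
    'example-data.R'
    'likelihood.R'
    'pipeline.R'
    'segmentation.R'
    'signatures.R'
    'simulate.R'
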