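Package: laiscan
Title: Local Ancestry Inference Benchmarking and Ancestry-Deviation Scans
    for Admixed Cohorts
Version: 0.1.0
Authors@R: person("Ana", "Sommer", email = "ana.sommer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating local ancestry inference (LAI) in
    two-way admixed cohorts, motivated by ancient-DNA applications where
    reference panels are small and unbalanced. Provides a synthetic-data
    generator for admixed haplotypes with exponential ancestry tracts laid
    down under a single admixture pulse, injected ancestry deviations,
    pseudohaploid sampling, genotype error and phase-switch error; two
    in-package LAI callers (a minimum-mismatch sliding-window classifier
    and a two-state haplotype HMM with posterior decoding); TRACTOR-style
    unkink rephasing and posterior filtering; global- and local-ancestry
    benchmarking statistics; exponential tract-length theory and
    maximum-likelihood dating of a single admixture pulse; and a
    covariance-corrected multi-method Z-score scan for loci with deviant
    ancestry, with replication testing and misclassification diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
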