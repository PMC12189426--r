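Package: ssblup
Title: Single-Step Genomic BLUP and Weighted Single-Step GWAS for
    Repeated Litter-Size Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of lowly heritable, repeatedly
    recorded litter-size traits in pig breeding populations where only a
    small core of a large pedigree is genotyped. Implements the
    repeatability animal model with pedigree-based relationships (Henderson
    mixed model equations, sparse A-inverse with Meuwissen-Luo inbreeding),
    single-step genomic BLUP through the H-inverse combination of pedigree
    and VanRaden genomic relationships, EM-REML variance-component
    estimation with average-information acceleration, bivariate genetic
    correlations, prediction-error-variance based expected accuracy with
    k-fold cross-validation, and the iterative SNP-weighted single-step
    GWAS with 0.3 Mb window decomposition of genetic variance and
    candidate-gene assignment.  A gene-dropping simulator generates
    pedigrees, LD-structured genotypes and multi-trait repeated litter
    records so the whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
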