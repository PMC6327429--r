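Package: kdrhap
Title: Fine-Scale Spatial and Temporal Dynamics of kdr Haplotypes in Aedes aegypti
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Statistical pipeline for surveillance of knockdown-resistance (kdr)
    alleles at codons 1534 and 1016 of the voltage-gated sodium channel in
    Aedes aegypti. Provides EM maximum-likelihood haplotype frequency
    estimation from unphased two-locus genotypes, linkage-disequilibrium
    statistics (D, r-squared, chi-square), chi-square heterogeneity tests of
    block- and sector-level frequencies with pairwise Yates-corrected
    comparisons, Moran's I spatial autocorrelation with inverse-distance
    weights, hierarchical linear mixed models for temporal and seasonal
    change, two-proportion power calculations for survey design, and a
    synthetic-study generator reproducing the block/sector/timepoint sampling
    design so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
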