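Package: seedcracker
Title: Haplotype Age Estimation and Candidate-Region Analyses for a
    Balanced Bill-Size Polymorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-genetic toolkit for studying a Mendelian bill-size
    polymorphism maintained by balancing selection, modelled on the seedcracker
    finch (Pyrenestes ostrinus) system. Implements forward Wright-Fisher
    simulation of allele-frequency trajectories under heterozygote advantage,
    a structured coalescent conditional on such trajectories with
    infinite-sites mutation, rejection-sampling approximate Bayesian
    computation (ABC) to estimate the age and equilibrium frequency of a
    balanced dominant haplotype, and the companion candidate-region analyses:
    allele-frequency-difference (delta) scans of pooled sequencing data,
    candidate-region bounding, gene-length-weighted bootstrap tests for
    private-allele enrichment, shared-polymorphism density scans for
    inversion breakpoints, and haplotype-dosage association with a
    quantitative trait. A synthetic-data generator produces truth-known
    cohorts, pooled allele-frequency tables and gene annotations with the
    statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
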