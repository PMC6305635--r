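Package: hapnet
Title: Haplotype Frequencies, Median-Joining Networks and Rho-Statistic Dating
    for Restriction-Site Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic analysis of binary restriction-site
    (RFLP) haplotypes such as the seven-site beta-globin gene-cluster
    haplotypes. Estimates haplotype frequencies from unphased diploid
    genotypes by an expectation-maximisation algorithm under Hardy-Weinberg
    equilibrium, builds median-joining networks (minimum-spanning-network
    backbone, iterative median-vector insertion, obsolete-node pruning) with
    edge-list, DOT and GraphML export, and dates haplotypes from a designated
    ancestral root with the rho statistic and its sigma standard error,
    converted to years under a user-supplied mutation-rate calibration.
    Includes Hardy-Weinberg genotype and star-genealogy simulators for
    validation, and an end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
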