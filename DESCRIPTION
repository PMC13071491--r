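Package: clinescan
Title: Geographic Cline Analysis for Secondary Contact Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits Szymura-Barton geographic cline models (sigmoid and
    stepped) to per-population allele frequencies along a transect,
    classifies clinal alleles by AICc evidence ratios against a uniform
    null, estimates Weir-Cockerham F_ST and isolation-by-distance
    neighbourhood size, tests candidate-SNP sets for enrichment of clinal
    alleles with frequency-matched hypergeometric tests, fits clines to
    normalised bioclimatic variables, and derives per-locus selection
    coefficients from cline width under migration-selection balance.
    Includes a seeded synthetic transect generator emulating a boreal
    contact-zone resequencing design, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    vcfR,
    geosphere,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
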