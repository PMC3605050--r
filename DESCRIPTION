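Package: hzcline
Title: Maximum-Likelihood Analysis of Geographic Clines in Hybrid Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits geographic allele-frequency clines (a central sigmoid with
    optional exponential tails) to per-population binomial allele counts along
    a one-dimensional transect by maximum likelihood, computes
    profile-likelihood (2-log-likelihood) support limits, and tests for
    differences in cline shape among loci with constrained likelihood-ratio
    tests under Bonferroni correction. Also provides supporting
    population-genetic computations for hybrid-zone studies: Weir-Cockerham
    F_ST between ecotypes, F2 recombination fractions and genetic map
    distances, exact contingency tests, phenotype-coded clines, projection of
    sampling localities onto a coastal transect, and seeded simulators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
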