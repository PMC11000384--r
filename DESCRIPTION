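Package: mendelburden
Title: Mendelian Disease Burden Analysis for Consanguineous Biobank Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the population burden of Mendelian disease
    variants in biobank-scale cohorts with substantial consanguinity and
    genetic substructure. Classifies known pathogenic/likely pathogenic (P/LP)
    variants by intersecting ClinVar and HGMD evidence, summarises carrier
    burden and homozygote enrichment by genetic subpopulation, computes
    cumulative gene carrier frequencies with screening-tier categories, screens
    for founder alleles, exceedingly common P/LP variants, depleted
    homozygosity and loss-of-function knockouts, flags homozygotes with extreme
    quantitative-trait values, and runs a covariate-adjusted gene-level
    rare-variant collapsing burden scan. A fully parameterised synthetic-cohort
    generator (inbreeding-model genotypes, database-style annotations,
    covariate-structured traits with spiked variant effects) makes the whole
    pipeline testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
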