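Package: dyadherit
Title: Maternal and Fetal Genetic Contributions to Quantitative Traits in
    Mother-Offspring Duos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-genetic analysis of mother-offspring duos:
    simulation of dyad cohorts with known maternal and fetal polygenic
    architecture under Balding-Nichols population structure; PLINK1 binary
    genotype input/output and marker quality control; immunoassay phenotype
    preparation with limit-of-detection handling; identity-by-state
    multidimensional-scaling ancestry coordinates; partitioning of duo
    genotypes into maternal non-transmitted and fetal non-inherited
    pseudo-haploid genomes; diploid and no-dosage-compensation haploid
    genetic relationship matrices; SNP-based heritability and genetic
    correlation by average-information REML with Fisher-scoring fallback and
    permutation nulls; per-SNP association scans with sub-population
    meta-analysis, conditional and dual-genome models; and case-control
    outcome and SNP-by-mediator interaction models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
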