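Package: cosegscan
Title: Rare-Variant Co-Segregation and Gene Burden Analysis for Familial
    Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A whole-exome prioritization pipeline for multiply affected
    families, motivated by familial cholesteatoma. Computes dual-caller
    consensus call sets (exact identity for single-nucleotide variants,
    fractional reciprocal interval overlap for indels), applies a
    rare/conserved/impactful/deleterious filtering cascade with a
    per-stage count ledger, intersects variants across affected family
    members to find co-segregating candidates, flags genes hit in two or
    more families, performs a gene-based collapsing mutation-burden test
    against public control allele counts (dominant and recessive models,
    two-sided exact test), and runs hypergeometric gene-set
    over-representation analysis. A fully specified synthetic-cohort
    generator with a machine-readable truth table makes every stage
    testable without access-controlled data.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
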