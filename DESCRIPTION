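Package: multixwas
Title: Multi-Omics Summary-Based Association and Evidence Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for x-wide association studies (xWAS)
    that link molecular quantitative trait loci (eQTL, sQTL, pQTL, mQTL,
    m6AQTL) to complex traits through GWAS summary statistics. Implements
    FUSION-style weighted imputation of molecular association z-scores,
    summary-data-based Mendelian randomization (SMR) with a Monte-Carlo
    HEIDI heterogeneity filter, allele harmonization and MHC-region
    exclusion, dictionary-style evidence-line curation with reliable-gene
    calling, windowed GWAS novelty classification, cross-QTL and
    cross-disorder replication metrics, and enumeration of multiple
    molecular regulation patterns (MMRP). A self-contained simulator
    generates LD-blocked genotypes, five molecular layers with partial
    cross-layer causal sharing, and mediated traits, so the whole pipeline
    is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
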