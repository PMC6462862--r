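Package: clonehet
Title: Multi-Region Tumor Heterogeneity, Mutational Signatures, and
    Germline DNA-Repair Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-region whole-genome analysis of metastatic
    tumors: somatic and germline variant filtration cascades, truncal
    versus private variant partitioning and clone-tree reconstruction,
    96-channel mutational-signature decomposition by non-negative least
    squares, loss-of-heterozygosity detection from variant allele
    frequencies and tumor cellularity, copy-number heterogeneity
    distances, and gene-by-environment association between germline
    DNA-repair variants and the tobacco mutational signature. Includes a
    synthetic multi-region cohort simulator with known ground truth so
    every stage is testable without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    ape,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
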