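Package: pdxscreen
Title: Integrated Genomic Analysis of Patient-Derived Xenografts and a
    Plasma CCND1/CDKN2A Copy-Number Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the genomic analysis of
    patient-derived xenograft (PDX) tumors and for a cell-free DNA
    copy-number biomarker of CDK4/6-inhibitor candidacy in nasopharyngeal
    carcinoma. Provides k-mer based deconvolution of mixed human/mouse
    sequencing reads, read-density copy-number estimation against a panel
    of normal white-blood-cell samples, amplicon-panel coverage filtering
    and gene-level copy-number calls, copy-number profile concordance,
    somatic single-nucleotide variant filtering and substitution-spectrum
    analysis, RPKM quantification with fold-change differential expression
    calling, and delta-delta-Ct quantification of plasma CCND1, CDKN2A and
    RAD52 copy numbers with regression of the CCND1/CDKN2A ratio on
    log10 Epstein-Barr virus DNA load. A seeded simulation layer generates
    every input the pipeline consumes, with planted truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
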