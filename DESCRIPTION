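Package: taascreen
Title: Tumor-Associated Antigen Discovery by Pan-Tissue Specificity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for strictly tumor-specific antigen candidates
    from multi-source RNA-seq tissue atlases. Implements relative-log-expression
    (median-of-ratios) normalization, a per-tissue negative-binomial
    likelihood-ratio screen aggregated into a minimum-fold-change tumor
    specificity statistic with Benjamini-Hochberg error control, triage of HLA
    class I immunopeptidome peptide-spectrum matches (score and mass-accuracy
    filtering, proteome-wide uniqueness scanning, HLA assignment constrained by
    sample typing and population allele frequency, isoform coverage), and qPCR
    relative expression against a multi-gene housekeeping reference. Includes a
    seeded synthetic-data generator emulating the statistical structure of
    pooled tumor/healthy tissue panels so every stage is testable offline.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
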