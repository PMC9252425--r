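Package: mybscope
Title: Curation, Classification and Regulatory-Network Analysis of
    R2R3-MYB Transcription-Factor Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide curation of plant R2R3-MYB
    transcription-factor families and their downstream functional
    analysis. Provides profile-based MYB repeat detection with
    landmark-tryptophan integrity rules, representative-isoform
    selection and chromosome-ordered gene naming, isoelectric point and
    molecular weight computation, protein-to-genome coordinate mapping,
    position-weight-matrix motif scanning with Poaceae clade
    classification, tree-anchored subfamily assignment, 2^-ddCt qPCR
    relative quantification with significance tiers, expression-matrix
    filtering and a stand-in differential-expression test, tree-ensemble
    (GENIE3-style) gene-regulatory-network inference with edge pruning
    and sub-network extraction, and hypergeometric GO enrichment with
    permutation FWER control. A synthetic-data module generates every
    input with planted ground truth so the full pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    ranger,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
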