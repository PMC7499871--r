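Package: pairedpanel
Title: Paired Primary-Tumor and Metastasis Copy-Number and Actionability
    Analysis for Targeted Capture Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired primary-tumor and bone-metastasis
    biopsies sequenced on a barcoded targeted capture panel. Collapses read
    records to unique molecules, computes GC-corrected RPKM-normalized
    per-target depth, segments tumor-versus-normal log ratios by circular
    binary segmentation, applies gene-level amplification and deletion
    calling rules, converts variant allele frequencies to purity-adjusted
    mutation copy numbers, scores the shared somatic fingerprint between
    matched tumor pairs, and maps alterations to drugs with clinical
    evidence levels. Includes a synthetic-cohort simulator with known
    clonal truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
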