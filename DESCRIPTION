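Package: utrscreen
Title: Design and Analysis of Massively Parallel Reporter Screens for 3' UTR Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for massively parallel reporter assays (MPRA) that test
    the post-transcriptional effect of 3' UTR single-nucleotide variants on
    mRNA abundance. Covers synthesis-ready oligo library design (rare-variant
    and motif saturation-mutagenesis layouts with restriction-site screening),
    UMI-based quantification of per-allele DNA and RNA molecule counts from
    structured paired-end reads, activity and relative-activity (lnFC) scoring
    with a negative-binomial likelihood-ratio caller, mechanistic statistics
    (hexamer enrichment, position-weight-matrix motif-strength change against
    shuffled nulls, miRNA target-site and eCLIP peak overlap, RBP binding-delta
    comparisons), permutation-based gene-set enrichment with optional
    length/GC-matched controls, and patient-level analytics (expression
    outliers, untranslated tumor mutational burden, tertile survival
    stratification). A seeded synthetic-data generator emulates every input so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
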