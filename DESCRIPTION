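Package: snvcohort
Title: Cohort-Scale Annotation, Cross-Referencing and Classification of
    Coding-Region Single Nucleotide Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bookkeeping side of a referral-laboratory gene
    screen: parsing and canonicalizing HGVS coding-DNA (c.) substitution
    strings, annotating variants against a transcript model (promoter,
    splice-site, intronic, missense, nonsense, synonymous), cross-referencing
    observed variants against local mutation-database snapshots to call novel
    variants, summarizing cohorts by self-reported ethnicity, and applying a
    stepwise rule-based clinical classification into five significance tiers.
    Includes a seeded synthetic-data generator that emulates a CFTR-like
    27-exon gene and a rare-variant-enriched referral cohort with recorded
    ground truth, and an end-to-end pipeline that emits diff-friendly TSV
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
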