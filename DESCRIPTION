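Package: mirseed
Title: Seed-Site Enrichment and Ranked-List Word Analysis for
    MicroRNA Target Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate microRNA targets from expression
    fold-change profiles. Derives the canonical seed-match site strings
    (6mer, 7mer-m8, 7mer-1A, 8mer) from a mature miRNA sequence, scans
    3'UTR collections with mutually exclusive site-type assignment,
    partitions genes into up-, down- and no-change sets by fold change
    with an optional between-array variance pre-filter, tests seed-site
    enrichment between the sets (gene-fraction Fisher exact tests,
    size-corrected resampled occurrence counts, per-kb site densities),
    ranks all k-mer words by a length-normalized running-sum
    overrepresentation statistic with a permutation Z-score, reports
    candidate target tables, and measures miRNA-mRNA expression
    anti-correlation. Includes a seeded synthetic-data generator that
    emulates the statistical structure of a miRNA overexpression
    microarray experiment so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
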