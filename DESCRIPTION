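Package: granuletx
Title: Genome-Resolved Metatranscriptomics of Anammox Granule Communities
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies gene expression across metagenome-assembled genomes
    (MAGs) recovered from anammox granular sludge. Implements
    intersection-strict assignment of mapped reads to ORFs, RPKM and
    median-relativized relative expression, per-genome abundance and
    expression fractions, MetaCyc-style pathway presence calls and pathway
    expression with min-over-complex-subunit and max-over-isozyme
    aggregation, denitrification marker-gene profiles, peptidase and
    transporter inventories, and amino-acid auxotrophy and biosynthetic-cost
    analyses. Includes a synthetic-community generator with known ground
    truth (Dirichlet composition, log-normal transcript levels, Poisson
    counts) that emits the pipeline's own input formats, so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
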