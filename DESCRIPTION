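Package: biomodules
Title: Biomodule Discovery from Chromatin Co-Occupancy and Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of chromatin mark co-occupancy and
    transcriptome data. Intersects ChIP-seq peak sets for two chromatin
    marks, links the co-enriched regions to candidate target genes on both
    sides within a search radius using the seq2gene strategy (bisection
    search over exon and transcript annotation tables), preprocesses
    expression matrices (probe collapse, empirical-Bayes batch adjustment,
    interquartile-range filtering), computes moderated-t differential
    expression and seed-gene co-expression statistics, extracts biomodules
    as genes jointly top-ranked in both orderings with a permutation-tested
    weighted overlap score, and tests biomodules for gene-set
    over-representation with a conditional hypergeometric test against the
    restricted assay-by-collection background. Includes seeded synthetic
    generators for every input so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    sva,
    optparse,
    yaml
Config/testthat/edition: 3
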