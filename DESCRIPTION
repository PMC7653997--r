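Package: awmfe
Title: Association Weight Matrix Analysis of Feed-Efficiency GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect the shared and specific genetic determinism of
    feed-efficiency criteria (residual feed intake, residual gain and the
    feed-efficiency ratio) in growing cattle. Derives the efficiency traits by
    residual regression, runs mixed-linear-model association with a genomic
    relationship matrix and fixed null-model variance components, builds
    association weight matrices (AWM) to select co-associated genes around a
    key phenotype, computes z-score genomic correlations between traits, and
    contrasts SNP-based heritabilities of selected versus random marker
    panels. A quantitative-genetic population simulator with target genetic
    correlations makes the whole pipeline testable without proprietary data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
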