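Package: meripr
Title: Downstream Analysis of MeRIP-seq m6A Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of methylated-RNA immunoprecipitation
    sequencing (MeRIP-seq) experiments with replicated IP/input libraries
    across conditions. Builds high-confidence consensus peaks from
    replicate narrowPeak calls (50 percent overlap of the shorter interval
    in at least two replicates), quantifies per-peak IP/input enrichment as
    fragments per million, assigns peaks to genes, profiles summit
    topology along a five-segment transcript partition and a metagene
    axis anchored at the coding sequence, scans RRACH consensus motifs
    around summits, calls stage-pairwise differential methylation and
    expression with pooled-variance t tests, and correlates methylation
    enrichment with gene expression. A fully ground-truthed synthetic
    data generator emulates the statistical structure of a three-stage,
    three-replicate liver m6A study so that every analysis stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
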