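Package: xenosplit
Title: Species-of-Origin Deconvolution and Downstream Analysis of Xenograft RNA-seq
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing RNA-seq of patient-derived xenografts, where
    human tumor reads are mixed with reads from supporting mouse tissue. Reads
    aligned to both the human and mouse genomes are classified as human, mouse
    or ambiguous by comparing best-alignment mismatch counts; species-partitioned
    alignments are quantified per gene by an exon-containment rule with
    counts-per-million normalization; human and mouse expression is joined over
    one-to-one orthologue pairs for correlation and hierarchical clustering;
    differential expression uses a conditional negative-binomial exact-style test
    with Benjamini-Hochberg false discovery rates, with Wallenius non-central
    hypergeometric gene-set enrichment; strand-stratified allele tallies at
    known variant loci and exponential tumor growth fits (doubling time, R
    squared) complete the pipeline. A synthetic-data generator produces paired
    orthologous references, truth-labeled reads, alignments, count matrices and
    growth series so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    data.table,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    rtracklayer,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
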