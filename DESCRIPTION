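Package: cotx
Title: Exon-Biased Occupancy Analysis of Co-Transcriptional ChIP-Seq Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of ChIP-seq and nascent RNA-seq coverage
    tracks for proteins that travel with elongating RNA polymerase II.
    Parses refGene-style gene annotations, applies isolation and
    duplicate-name filters, reads and queries Bedgraph coverage tracks,
    converts BED read alignments to RPKM expression classes, builds
    scaled metagene occupancy profiles (per-base flanks plus binned gene
    bodies), and computes the input-normalised exon versus intron
    enrichment statistic with Wilcoxon rank-sum testing, percent-length
    profiles and cross-track exon correlations.  A seeded synthetic-data
    generator produces annotations, reads and matched ChIP/input tracks
    with known ground truth so that every stage is verifiable by
    parameter recovery without access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
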