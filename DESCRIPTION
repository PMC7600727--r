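Package: micropoly
Title: Microsatellite Discovery and Length-Polymorphism Calling from
    SSR-Enriched Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering simple sequence repeats (SSRs,
    microsatellites) and their length polymorphisms (SSLPs) from paired-end
    sequencing of SSR-enriched genomic libraries. Quality-trims and merges
    overlapping read pairs, scans merged sequences and reference genomes for
    maximal perfect tandem repeats of 2-6 bp units with MISA-style minimum
    repeat thresholds, canonicalizes repeat motifs into strand/rotation
    classes, masks repeat tracts and clusters sequences by flank similarity
    to count distinct tract lengths per locus (the SSLP statistic), anchors
    polymorphic loci to a reference genome via their flanks, intersects loci
    across populations, and classifies loci by gene region from GFF3 gene
    models. Includes a synthetic-data generator that plants SSR loci with
    known multi-population allele sets so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
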