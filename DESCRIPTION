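Package: segvir
Title: Reconstruction of Segmented RNA Virus Genomes from dsRNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct complete multipartite RNA virus genomes from
    double-stranded RNA sequencing libraries that preserve genome segment
    termini (FLDS-type protocols). Provides adapter trimming and quality
    filtering, read-to-contig alignment ingestion plus a minimal built-in
    mapper, read start/stop pileups, terminus calling from dominant read-stop
    positions, full-length segment classification, genome binning by
    conserved 5'/3' terminal sequences, strain-level segment pairing by
    sample co-occurrence and abundance similarity, and gene annotation
    (ORF calling under the bacterial genetic code, Shine-Dalgarno motif
    detection, RNA-directed RNA polymerase catalytic-motif scanning and a
    hydropathy-based transmembrane flag). Includes a synthetic segmented
    virome and FLDS read simulator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    BiocGenerics,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
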