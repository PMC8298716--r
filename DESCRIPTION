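Package: placentapiR
Title: Characterization of Tissue piRNA Transcriptomes from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for characterizing PIWI-interacting RNA
    (piRNA) expression in a tissue cohort from small RNA sequencing reads:
    read-level quality control (adapter trimming, length window, Phred floor,
    miRNA-length exclusion), exact-sequence assignment of reads to annotated
    piRNAs, reads-per-million normalization, a two-criterion consistent
    expression filter, locus-multiplicity classification of multi-mapping
    piRNAs, genomic region membership (piRNA clusters, mitochondrial genome,
    imprinted regions), and cross-tissue specificity analysis (detection
    vectors, exclusivity and fold-bias classes, hierarchical clustering with
    dendrogram node extraction, and t-SNE embedding). Includes a synthetic
    cohort generator with a planted truth table so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stringi,
    jsonlite,
    ape,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
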