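Package: prclip
Title: Crosslink-Site Analysis and RNA-Binding Kinetics for Dipeptide
    Repeat iCLIP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of iCLIP-style protein-RNA crosslinking
    data for arginine-rich dipeptide repeat proteins: demultiplexing and
    UMI-based PCR-duplicate collapsing, truncation-model crosslink-site
    assignment, counts-per-million normalisation, permutation-FDR calling
    of significant crosslink sites, control-aware gene-level binding
    quantification and region annotation, pentamer motif enrichment
    around crosslink sites against a matched within-gene background, and
    1:1 Langmuir equilibrium fitting of biolayer-interferometry binding
    data. Ships a synthetic-data generator (toy transcriptome, CLIP
    libraries with ground truth, simulated association traces) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
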