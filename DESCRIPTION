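Package: trabiseq
Title: Strand-Resolved Mapping and Quantification of DNA Single-Strand Breaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of 3'-OH capture sequencing (GLOE-seq style)
    experiments that map DNA single-strand breaks at single-nucleotide,
    strand-resolved precision. Converts UMI-tagged aligned reads into
    deduplicated break signals, normalizes break counts per gene, strand and
    genomic bin against the endogenous background of unexpressed genes,
    builds metagene and TSS-anchored break profiles (including the divergent
    transcription branch upstream of promoters), characterizes sequence
    context at incision sites, and validates break calling against
    nicking-endonuclease ground truth. Ships a synthetic-data generator that
    plants break landscapes with known structure so every stage of the
    pipeline can be tested against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
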