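Package: plastmine
Title: Comparative Plastome Micro-Variation Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines molecular markers from sets of closely related chloroplast
    genomes. Delimits the quadripartite plastome structure (LSC, IRb, SSC, IRa)
    by exact inverted-repeat detection, calls single-nucleotide polymorphisms
    from a multiple alignment with a six-class transition/transversion
    substitution spectrum, detects simple sequence repeats with MISA-style
    per-motif-length unit thresholds and calls cross-genotype repeat-length
    polymorphisms, classifies alignment indels into SSR-related and common
    events with reference-polarized direction, and verifies small inversions by
    the flanking inverted-repeat (stem-loop) rule. A plastome simulator plants
    every event class with a ground-truth ledger so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
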