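Package: aselong
Title: Allele-Specific Expression Analysis for Spliced Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns spliced long-read alignments to parental haplotypes by
    majority vote over phased exonic single-nucleotide variants, quantifies
    maternal and paternal expression per gene and per isoform with stranded
    union-mode counting, classifies genes as maternally, paternally or
    biallelically expressed with hard allelic-ratio cutoffs, detects
    X-inactivation escape candidates under a skewed-XCI design, and compares
    allelic call tables between platforms. Includes a deterministic synthetic
    F1-hybrid data generator (diploid genome, phased SNVs, annotation, spliced
    alignments) with known allelic truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    BiocGenerics,
    tools,
    utils,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
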