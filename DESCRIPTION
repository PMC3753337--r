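Package: svbreaks
Title: Structural Variant Breakpoints, Junction Microhomology and
    Chromothripsis from Mate-Pair Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect large genomic rearrangements from mate-pair
    read-pair signatures, resolve breakpoint junctions at base-pair
    resolution, and characterise the repair signatures they carry.
    Includes a paired-end-mapping (PEM) signature caller that clusters
    discordant read pairs into typed structural-variant links, a
    windowed read-depth copy-number profiler with binary segmentation, a
    gene-impact annotator (truncation, chimera, promoter and intronic
    categories), a junction resolver that classifies junctions into
    microhomology, blunt, untemplated-insertion, genomic-shard and
    templated-insertion patterns, a closed-form null model with
    chi-square enrichment tests for junction microhomology, breakpoint
    motif and composition enrichment scans, an expressed-rearrangement
    test from RNA-seq read pairs, and a chromothripsis detector based on
    two-state copy-number oscillation and breakpoint clustering. A
    first-class simulator generates rearranged genomes (simple events
    and chromothripsis) with ground-truth junctions, mate-pair and
    RNA-seq read pairs, so every stage is testable end to end. All
    tabular inputs and outputs are tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
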