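Package: mitostructr
Title: Structural Assessment of Plant Mitochondrial Genome Assemblies from
    Paired-End Read Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate the structure of organelle (chiefly plant
    mitochondrial) genome assemblies using paired-end read evidence: a seeded
    gapless read mapper enforcing 90 percent length / 90 percent identity
    match criteria (or ingestion of external SAM/BAM alignments), per-base
    depth-of-coverage profiling with spike and dip detection, classification
    of read pairs as consistent or inconsistent with the library insert
    model, clustering of inconsistent pairs into candidate structural
    junctions, and inference of genome topology (single circular map,
    two circles bridged by a substoichiometric linear segment, linear, or
    unresolved) with relative copy-number estimation. Also provides
    thresholded homology scanning for dispersed repeats, plastid-derived
    segments (MIPTs) and gene location, conserved-block trimming of multiple
    sequence alignments with relaxed settings plus batch concatenation for
    multi-gene matrices, and a synthetic-data module that generates genomes,
    planted features, multi-isoform topologies and paired reads with
    machine-readable truth tables so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
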