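Package: uorfkit
Title: Upstream Open Reading Frame Detection, Ribo-Seq Evidence Scoring,
    and Steric Block Antisense Oligonucleotide Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for screening transcripts for upstream open reading
    frames (uORFs) and designing steric block antisense oligonucleotides
    (ASOs) against them. Builds spliced transcript models from genome
    FASTA plus GTF/GFF3/refFlat annotation, detects and classifies uORFs
    in 5' UTRs (upstream, pORF-overlapping, N-terminal extension),
    ablates uORF start codons in silico, aggregates ribosome profiling
    coverage tracks and projects them onto transcript coordinates to
    score uORF translation evidence, designs uORF-start-anchored ASOs
    with uniform or gapmer chemistry patterns and chemistry-preserving
    scrambled controls, computes expected masses of modified
    oligonucleotides from elemental composition for mass-spectrometry QC,
    and implements efficiency-corrected relative qPCR quantification
    (Pfaffl) and dual-luciferase / loading-control normalization. A
    deterministic simulator generates genomes, annotations, coverage
    tracks and quantification tables with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
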