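Package: tsrkit
Title: Calling and Classifying Transcription Start Regions from Nascent
    5'-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls single-nucleotide transcription start sites (TSSs) and
    clustered transcription start regions (TSRs) from capped small RNA
    sequencing (csRNA-seq) 5'-end profiles, filters false positives with the
    short-RNA input library, classifies each TSR's transcript as stable or
    unstable from total RNA-seq coverage, annotates genomic context relative
    to gene 5' ends, pairs divergent TSRs into bidirectional units with
    initiation styles (S/U/US/UU), and integrates STARR-seq enhancer
    activity with per-bp normalization and Tukey HSD group comparisons.
    Includes sequence-feature utilities (hexamer stability-ratio ranking,
    IUPAC consensus scanning, nucleotide metaplots), signal metrics (pausing
    index, metaplots, windowed log-ratios), and a seeded synthetic-data
    generator that plants TSRs with known class labels so every stage of the
    pipeline can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
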