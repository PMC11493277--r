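Package: nascentr
Title: Nascent Transcription Profiling and Splicing Efficiency from mNET-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing nascent-transcription sequencing (mNET-seq)
    and companion RNA-seq data at single-nucleotide resolution: extraction of
    RNA polymerase II positions from properly paired alignments (the 3' end of
    the second mate, stranded by the first), strand-specific binned coverage
    with RPKM normalisation, CIGAR-based per-gene splicing efficiency with
    rank-based condition comparisons, three-way gene classification
    (intron-containing, intronless, histone) with most-expressed-isoform
    selection and an expression filter, scaled-gene metagene profiles, a
    downstream-of-poly(A) readthrough index for termination defects, and the
    standard bench-assay quantifications (ChIP percent input, delta-delta-Ct
    relative expression, western-blot normalisation, differential-expression
    significance calls). A fully parameterised synthetic-data generator
    emulates the statistical structure of such experiments (promoter-proximal
    pausing, uniform gene-body signal, exponential post-poly(A) readthrough,
    per-gene intron retention) so every stage is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils,
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
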