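Package: teiscan
Title: Transposable Element Insertion Calling from Paired-End Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects non-reference transposable element insertions (TEIs) at
    single-nucleotide resolution from coordinate-sorted paired-end BAM
    alignments and a reference TE annotation in GFF3. Discordant read pairs
    with one uniquely mapped "anchor" read and one mate in an annotated TE
    are clustered per strand; paired forward/reverse clusters define an
    insertion interval that soft-clipped reads refine to a breakpoint.
    Zygosity (variant allele fraction) is estimated as the ratio of clipped
    to clipped-plus-spanning reads, calls are filtered with cutoffs derived
    from the sequencing-library statistics, and matched tumor/normal pairs
    can be compared to classify somatic insertions. Includes a deterministic
    aligner-emulating read simulator and an evaluation harness for
    benchmarking sensitivity, precision, breakpoint accuracy and zygosity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
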