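Package: ribopause
Title: Ribosome Pause-Site Detection, Translation-Dependent Decay Indices and
    Compositional Bias Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for transcription/translation-inhibition time
    courses and ribosome profiling. Computes a translation-dependent decay
    (TDD) index per mRNA from inhibitor time-course count tables using
    stable-gene median-of-ratios normalization, calls differential ribosome
    pause peaks from RNA-normalized Ribo-seq coverage with a
    mean-plus-three-SD threshold and replicate score filters, tests codon and
    amino-acid compositional biases with matched-control randomization tests
    and zero-inflated beta regression, performs empirical amino-acid
    enrichment of protein lists against proteome-sampled controls, and
    tallies low-frequency transcriptional mutations from pileup tables. A
    synthetic-data generator emulates the structure of each input so the
    whole pipeline runs and is validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
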