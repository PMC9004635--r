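Package: ribogridkit
Title: Transcript-Centric Ribosome Profiling Quantification via Ribogrid Count Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcript-centric analysis of ribosome profiling
    (Ribo-seq) data: barcode demultiplexing and UMI extraction for multiplexed
    libraries, trimming of non-templated 5' mismatches from transcriptome
    alignments, construction of per-transcript ribogrid count matrices
    (footprint counts indexed by read length and 5'-end position) stored in a
    documented HDF5 schema, A-site assignment by per-read-length displacement
    anchored at either read end, codon-level densities, reading-frame and
    metagene/periodicity statistics, gene-level counts and TPM, static
    visual summaries, and a fully seeded footprint simulator with a
    ground-truth manifest that serves as a test oracle for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    rhdf5,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
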