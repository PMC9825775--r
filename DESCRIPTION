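Package: scbatch
Title: Batched Per-Cell BAM Extraction and Command Execution for Pooled
    Single-Cell Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streams a pooled, cell-barcoded single-cell RNA-seq BAM file and
    extracts per-cell BAM files ("scBAMs") in configurable batches, executing a
    user-supplied shell command on each scBAM with a bounded worker pool.
    Extraction of the next batch is interleaved with command execution, so
    memory and open-file usage are bounded by the batch size while
    multiprocessor throughput stays high. Cell barcodes can be pulled from BAM
    tags (CB, CR or any custom tag) or from delimited tokens or regular
    expressions applied to the read name, covering CellRanger, STARsolo and
    UMI-tools conventions. Runs can be restricted to an acceptance list of
    barcodes, to genomic regions, or to a maximum number of cells. Includes a
    deterministic synthetic-fixture generator so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    rtracklayer,
    tibble,
    yaml,
    optparse,
    generics,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
SystemRequirements: samtools (for reading alignment streams and as an
    independent cross-check in the test suite)
Config/testthat/edition: 3
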