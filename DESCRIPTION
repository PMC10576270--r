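Package: atacrecall
Title: Superlist Re-Calling and Chromatin State Classification for ATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-calls weak ATAC-seq peaks by quantifying depth-normalized
    tag density over the union ("superlist") of peaks called in any library,
    annotates every peak open or closed per library at a density threshold,
    partitions peaks into cell-state sets (both-open, naive-specific,
    primed-specific) and, with transcription-factor ChIP-seq peaks, into
    the four dynamic groups C1-C4. Includes the downstream statistics used
    to characterise the groups (row-wise Z scores, Mann-Whitney U tests,
    summit-centered pileup profiles, moving-average binding density over
    ranked genes, fold-change screens, motif-table filtering), TSS-proximity
    peak-to-gene annotation, a config-driven synthetic-data generator with
    ground truth for end-to-end validation, and a pipeline orchestrator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
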