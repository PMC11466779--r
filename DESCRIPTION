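Package: triomics
Title: Multi-Omic Integration of Chromatin Loops, Open Chromatin and
    Expression Between Disease Timepoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing two disease timepoints (diagnosis and
    relapse) across three omic layers: differential chromatin-loop
    analysis on loop-strength matrices using trimmed-mean-of-M-values
    normalization and empirical-Bayes moderated t-statistics,
    derivation of reproducible state-specific open-chromatin regions
    from replicate ATAC-seq peak calls, two-group differential gene
    expression, and a multi-omic integration stage that links
    state-specific loop anchors to accessible peaks and nearby genes,
    measures enrichment of differential expression against random
    gene sets, and tests loss of repressive-mark (H3K27me3) contacts
    with a width- and chromosome-matched permutation null. Includes a
    synthetic-data generator with planted ground truth so the whole
    pipeline can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    optparse
Config/testthat/edition: 3
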