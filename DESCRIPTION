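Package: loopdyn
Title: Chromatin Loop Dynamics and Multi-Enhancer Dominance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of time-course HiChIP loop sets and matched
    multi-omics signal around an acute transcription-factor stimulation.
    Builds a cis-regulatory-element (CRE) regulatory network from accessibility
    summits and mark-specific loop tables, TMM-normalizes per-timepoint contact
    frequencies, quantifies bootstrapped contact-frequency fold changes from
    promoter and enhancer viewpoints, evaluates average/maximum/sum
    multi-enhancer summarization models against expression, calls "dominant"
    loops by min-max-scaled contact frequency with a Gini inequality score,
    and groups nascent-transcription responses by maximal-expression time
    point. Ships a synthetic multi-omics generator with planted ground truth
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
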