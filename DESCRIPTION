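Package: medinet
Title: Network Diffusion for Multi-Omics Mediator Detection
Version: 0.1.0
Authors@R:
    person("medinet", "developers", email = "medinet@example.org", role = c("aut", "cre"))
Description: Detects downstream 'mediator' genes that relay the effects of
    per-tumor upstream aberrations (somatic mutations, dysregulated miRNAs)
    to downstream molecular changes (mRNA, protein and phosphosite
    differential expression) over a directed functional interaction network.
    Implements sample-specific bidirectional insulated diffusion (random walk
    with restart), cohort-level rank aggregation, a permutation-based
    empirical false discovery rate, somatic variant filtering, multi-omic
    event-combination rules, and a synthetic multi-omics cohort generator
    with planted mediators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    data.table,
    jsonlite,
    matrixStats,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
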