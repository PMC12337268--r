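Package: pavnet
Title: Presence-Absence Variation and Coupled Coexpression Networks from Dual
    Host-Symbiont Nodule Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers presence-absence variation (PAV) of symbiont genes from
    dual host-symbiont nodule RNA-seq counts, groups candidate genes into
    syntenic clusters, tests clusters and genes against host partner-quality
    traits, partitions a pangenome into core/shell/cloud frequency classes,
    builds weighted gene coexpression networks (topological overlap, module
    eigengenes) for both organisms from strain-mean logCPM, and correlates
    modules with traits and across kingdoms. Includes a negative-binomial
    synthetic-data generator with planted clusters, planted modules, simulated
    assemblies and a recorded ground truth, plus evaluation metrics, so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
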