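Package: phosnet
Title: Kinase-Substrate Network Inference from Differential Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers regulated kinases and kinase-substrate networks from a
    differential phosphosite table. Phosphosite sequence windows are scored
    against a library of kinase position-specific scoring matrices and
    percentile-ranked; kinase-motif enrichment among up- and down-regulated
    sites is assessed with one-sided Fisher exact tests and Benjamini-Hochberg
    correction, yielding signed relative kinase activities. Kinase library
    scores (KLS) are augmented with curated kinase-substrate evidence and
    interaction reference counts, multiplied by a signed differential-regulation
    score to give final kinase-substrate interaction scores, and aggregated to
    kinase-substrate and pathway interaction scores for network export.
    Companion modules provide hypergeometric overrepresentation analysis with
    gene-dependency partitioning, extracellular-flux (mitochondrial and
    glycolysis stress test) metrics, isotopologue fractional abundances, and a
    synthetic-data generator with planted ground truth for validating every
    stage by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
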