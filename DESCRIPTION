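Package: sharedmiR
Title: Shared-Disease miRNA Prioritization, Enrichment, Network Hubs and
    qPCR Quantification with Planted-Truth Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for prioritizing microRNAs shared between
    two diseases. Builds per-disease gene sets from DisGeNET-style
    association tables and intersects them, aggregates multi-source
    miRNA-target predictions and ranks miRNAs by shared-target count,
    performs hypergeometric over-representation analysis with
    Benjamini-Hochberg correction against GMT libraries, builds
    interactome-restricted target networks with degree-ranked hubs and a
    degree-sorted circular layout, and computes efficiency-adjusted
    (Pfaffl-type) qPCR relative expression with spike-in quality control,
    one-way ANOVA with Fisher's LSD, t-tests and fold changes of group
    means, plus ELISA total-protein normalization. Every input can be
    simulated with planted ground truth (exact disease-set overlap, planted
    high-shared-target miRNAs, planted enriched terms, planted network hubs,
    planted log2 fold changes) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    rlang,
    igraph,
    jsonlite,
    yaml,
    fgsea,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
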