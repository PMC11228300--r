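Package: cofosnet
Title: Brain-Wide cFos Co-Activation Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds inter-regional co-activation networks from whole-brain
    immediate-early-gene (cFos) cell-count data. Converts per-animal regional
    counts to volume-normalized densities, screens per-region group
    differences (Shapiro-Wilk, Welch t, Benjamini-Hochberg FDR), estimates
    per-genotype Spearman rank-correlation matrices with exact small-sample
    permutation p-values, thresholds them into binary adjacency matrices,
    and reports network density, signed edge counts, threshold sweeps and
    functional-subnetwork edge lists. Includes a Gaussian-copula synthetic
    cohort generator with planted rank-correlation blocks, a zone-occupancy
    trial simulator, and the standard rodent social-behavior indices
    (sociability and social-novelty preference, spontaneous alternation,
    elevated-plus-maze open-arm ratio, interaction-bout metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
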