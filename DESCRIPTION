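Package: holodepth
Title: Depth-Gradient Analysis of Sponge Holobiont Microbiomes and Metabolomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for studying how depth and water mass
    structure sponge-associated prokaryotic communities and holobiont
    metabolomes. Provides untargeted LC-MS feature-table filtering
    ("cleaned", "pc_group", "ion"), monotone depth-trend classification of
    ASVs and metabolite features with FDR control, detection of sister-group
    ASV ecotypes (near-identical sequence pairs with opposing depth
    responses), community statistics (alpha diversity, Bray-Curtis,
    PERMANOVA, metric ordination with environmental vector fitting, VIF
    screening, UPGMA clustering), OPLS regression of depth on feature
    matrices with seven-fold Q2, permutation pQ2 and VIP scores, consensus
    positive co-occurrence networks from five association estimators
    (Pearson, Spearman, SparCC, local similarity, MIC) with 4-of-5 voting,
    and microbe-metabolite integration (Mantel, Procrustes, Spearman
    compound linking). Includes a synthetic holobiont data generator with a
    planted-truth ledger so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    vegan,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
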