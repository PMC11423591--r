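Package: planktonet
Title: Assembly Processes, Niche Breadth and Co-Occurrence Network Stability
    of Plankton Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect how prokaryotic and eukaryotic plankton
    communities are organised along coastal environmental gradients.
    Implements abundant/rare sub-community partitioning, alpha diversity
    (including Faith's phylogenetic diversity), Mantel tests, Levins niche
    breadth, Sloan neutral community model fitting, phylogenetic null-model
    assembly inference (SES MNTD, beta-MNTD, beta-NTI, Raup-Crick on
    Bray-Curtis, process-fraction classification), correlation-based
    co-occurrence network construction with module detection and node
    roles (Zi-Pi), and removal-based network stability analysis
    (robustness, vulnerability, fragmentation). A synthetic-data module
    generates communities under neutral, selective, and mixed assembly
    with known ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
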