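Package: mfnet
Title: Soil Multifunctionality and Cross-Kingdom Microbial Co-Occurrence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking soil ecosystem multifunctionality to microbial
    community structure in manipulative field designs. Implements ecosystem
    multifunctionality indices (averaging, group-weighted, principal
    coordinate), community assembly statistics (rarefaction-based richness,
    Levins' niche breadth, a null-model normalized stochasticity ratio, and
    Sloan's neutral community model fit), random-matrix-theory thresholded
    cross-kingdom correlation networks with greedy modularity clusters,
    per-sample subnetwork topology and a network-complexity index, network
    stability metrics (robustness under node removal, vulnerability,
    relative modularity), and driver analyses (Spearman screening, random
    forest permutation importance, partial correlations). A seeded synthetic
    community generator reproduces the statistical structure such studies
    assume so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    minpack.lm,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
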