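Package: pseudopath
Title: Cluster-Based Minimum Spanning Tree Pseudotime Reconstruction for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Orders single cells along pseudo-temporal trajectories by
    clustering cells in a reduced expression space, connecting cluster
    centers with a minimum spanning tree, and projecting cells onto the
    tree backbone. Includes gene-module preprocessing with a piecewise
    linear rule for selecting the number of principal components,
    model-based (Gaussian mixture) cell clustering with BIC model
    selection, spline-based differential expression testing along
    pseudotime, a synthetic trajectory simulator, and a quantitative
    evaluation framework (pseudo-temporal ordering score, ordering
    similarity, perturbation robustness, gold-standard gene ranking).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mclust,
    mgcv,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
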