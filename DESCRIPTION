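Package: linksp
Title: Scalable Similarity-Popularity Link Prediction for Complex Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts missing links in undirected networks with a global,
    parameter-free similarity-popularity method: node popularity and the
    attraction induced by common neighbourhoods are estimated from degrees,
    factored out of the topology through an induced edge-length map, and the
    residual dissimilarity between non-adjacent nodes is measured by
    hop-bounded weighted shortest paths. Includes seven classical local
    similarity indices (Adamic-Adar, common neighbours, Cannistraci-Hebb,
    hub promoted, Jaccard, preferential attachment, resource allocation),
    an edge-removal evaluation framework (top-precision, AUROC, AUPR,
    relative top-precision, significant-rank aggregation with paired t-tests
    and Mann-Whitney-Wilcoxon/Benjamini-Yekutieli comparisons), seeded
    synthetic network generators (Barabasi-Albert, Watts-Strogatz,
    nonuniform popularity-similarity optimisation), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
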