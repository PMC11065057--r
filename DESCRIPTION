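Package: usfc
Title: Unified Structural and Functional Connectivity Traffic Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds "traffic maps" of the brain by unifying structural and
    functional connectomes. For every functional connection between two
    regions the most efficient structural route is found by minimising the
    summed cost (Euclidean distance divided by structural connectivity
    strength) over routes of up to four steps; functional load is then
    accumulated onto every structural segment each route traverses. The
    package provides readers and writers for atlas tables and connectivity
    matrices, a reproducible synthetic connectome generator with planted
    ground truth, hop-limited minimum-cost pathway search with an exhaustive
    oracle, group-level edge statistics with FDR control, regional and
    network load summaries with IQR outlier detection, step-stratified
    Spearman coupling between route-mean structural and functional
    connectivity, and weighted graph-theory metrics (efficiency, betweenness
    centrality, modularity) with cross-connectome comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
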