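Package: arcnets
Title: Phylogenetic Networks from Arc-Decorated Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction, enumeration and classification of rooted binary
    phylogenetic networks obtained by placing k arcs between the edges of a
    rooted binary phylogenetic tree with an ancestral root edge. Provides
    exhaustive enumeration and uniform sampling of k-fold decorated trees,
    classification of the resulting directed graphs (cyclic, tree-child,
    normal, hybridization), canonical forms for leaf-labeled networks,
    exhaustive census pipelines reproducing exact network counts, exact
    closed-form and asymptotic counting formulas, an exact rational
    truncated-series engine for the associated exponential generating
    functions, and seeded Monte Carlo estimation of class proportions
    beyond exhaustive reach. Reads and writes Newick and extended Newick.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
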