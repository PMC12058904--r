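# Shared fixtures and independent reference implementations used as oracles.

# hand-built decoration objects (vertex convention: leaves 1..n, root n+1,
# internals n+2..2n, subdivision pair i = (2n+2i-1, 2n+2i))
make_decoration <- function(newick, tk_edges, pairs) {
    base <- read_newick(newick)
    arcnets:::new_decoration(base, tk_edges, matrix(pairs, ncol = 2, byrow = TRUE))
}

# cherry on two leaves: edges (3,4),(4,1),(4,2)
cherry2 <- function() read_newick("(1,2);")

balanced4 <- function() read_newick("((1,2),(3,4));")
caterpillar4 <- function() read_newick("(1,(2,(3,4)));")

# decoration of the 2-leaf cherry with p1 on edge 4->1 and p'1 on edge 4->2
# (induced subdivision tree = MRCA plus two leaves, ell = 0)
cherry_dec_sides <- function() {
    make_decoration("(1,2);",
                    rbind(c(3L, 4L), c(4L, 5L), c(5L, 1L), c(4L, 6L), c(6L, 2L)),
                    c(5L, 6L))
}

# p'1 on the half-edge directly below p1 (single-edge subdivision tree,
# ell = 1; the arc is parallel to the tree edge 5->6)
cherry_dec_stacked <- function() {
    make_decoration("(1,2);",
                    rbind(c(3L, 4L), c(4L, 5L), c(5L, 6L), c(6L, 1L), c(4L, 2L)),
                    c(5L, 6L))
}

# p'1 on the root edge above p1: the arc targets an ancestor of its source,
# forcing a directed cycle
cherry_dec_cycle <- function() {
    make_decoration("(1,2);",
                    rbind(c(3L, 6L), c(6L, 4L), c(4L, 5L), c(5L, 1L), c(4L, 2L)),
                    c(5L, 6L))
}

# two reticulations directly below the cherry vertex, both sources on the
# root edge: vertex 4 has two reticulation children (not tree-child)
cherry_dec_two_retic_children <- function() {
    make_decoration("(1,2);",
                    rbind(c(3L, 5L), c(5L, 7L), c(7L, 4L), c(4L, 6L), c(6L, 1L),
                          c(4L, 8L), c(8L, 2L)),
                    c(5L, 6L, 7L, 8L))
}

# ----------------------------------------------------------- igraph oracles

net_igraph <- function(net) {
    igraph::graph_from_edgelist(net$edges, directed = TRUE)
}

ref_is_dag <- function(net) igraph::is_dag(net_igraph(net))

# label-preserving isomorphism via VF2 with leaf labels as colours
# (only valid on simple graphs, i.e. networks without parallel edges)
ref_isomorphic <- function(a, b) {
    col <- function(net) {
        nv <- net$nv
        ifelse(seq_len(nv) <= net$n, seq_len(nv), 0L)
    }
    igraph::isomorphic(net_igraph(a), net_igraph(b), method = "vf2",
                       vertex.color1 = col(a), vertex.color2 = col(b))
}

# independent R reimplementation of the fine classification (igraph for
# acyclicity and reachability), used to cross-check the compiled classifier
ref_classify <- function(net) {
    g <- net_igraph(net)
    if (!igraph::is_dag(g)) return("cyclic")
    nv <- net$nv
    ind <- tabulate(net$edges[, 2], nbins = nv)
    outd <- tabulate(net$edges[, 1], nbins = nv)
    tree_child <- all(vapply(which(outd > 0), function(v) {
        kids <- net$edges[net$edges[, 1] == v, 2]
        any(ind[kids] <= 1)
    }, logical(1)))
    if (!tree_child) return("not_tree_child")
    has_shortcut <- any(vapply(seq_len(nrow(net$edges)), function(e) {
        g2 <- igraph::delete_edges(g, e)
        net$edges[e, 2] %in%
            igraph::subcomponent(g2, net$edges[e, 1], mode = "out")
    }, logical(1)))
    if (has_shortcut) return("shortcut")
    # temporal existence: merge reticulations with parents, quotient DAG test
    comp <- seq_len(nv)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    for (e in seq_len(nrow(net$edges)))
        if (ind[net$edges[e, 2]] >= 2) {
            a <- find(net$edges[e, 1]); b <- find(net$edges[e, 2])
            if (a != b) comp[a] <- b
        }
    tree_e <- which(ind[net$edges[, 2]] <= 1)
    cls_u <- vapply(net$edges[tree_e, 1], find, integer(1))
    cls_v <- vapply(net$edges[tree_e, 2], find, integer(1))
    if (any(cls_u == cls_v)) return("normal_not_hyb")
    q <- igraph::graph_from_edgelist(cbind(match(cls_u, unique(c(cls_u, cls_v))),
                                           match(cls_v, unique(c(cls_u, cls_v)))),
                                     directed = TRUE)
    if (igraph::is_dag(q)) "hybridization" else "normal_not_hyb"
}

# all decorated trees of the full (n,k) universe as network objects,
# via the R-level enumeration route (independent of cpp_census)
enumerate_networks <- function(n, k) {
    out <- list()
    for (tr in enumerate_trees(n))
        for (d in enumerate_decorations(tr, k))
            out[[length(out) + 1L]] <- as_network(d)
    out
}
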