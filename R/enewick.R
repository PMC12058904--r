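# Extended Newick (eNewick) I/O. Each reticulation vertex appears twice
# under a shared #Hj tag: once carrying its subtree ("(A)#Hj") and once as a
# bare reference ("#Hj"). Plain trees serialize to plain Newick.

#' Write a network as an extended Newick string
#'
#' Reticulation vertices are emitted twice under a shared `#Hj` tag; the
#' occurrence reached first in the traversal carries the reticulation's
#' subtree, the other is a bare tag. Children are ordered by the smallest
#' descendant leaf label, so the output is deterministic. The graph must be
#' acyclic.
#'
#' @param x An `arcnets_network` (or coercible via [as_network()]).
#' @return A single eNewick string (plain Newick when k = 0).
#' @seealso [read_enewick()]
#' @export
write_enewick <- function(x) {
    net <- as_network(x)
    .stop_if_cyclic(net, "eNewick serialization")
    nv <- net$nv
    ind <- .indeg(net$edges, nv)
    ch <- .children(net$edges, nv)
    # smallest descendant leaf per vertex (reticulations traversed freely)
    minleaf <- rep(NA_integer_, nv)
    rec_min <- function(v) {
        if (!is.na(minleaf[v])) return(minleaf[v])
        m <- if (v <= net$n) v else min(vapply(ch[[v]], rec_min, integer(1)))
        minleaf[v] <<- m
        m
    }
    tagno <- integer(nv)
    ntags <- 0L
    rec <- function(v) {
        if (v <= net$n) return(as.character(v))
        if (ind[v] >= 2L) { # reticulation
            if (tagno[v] == 0L) {
                ntags <<- ntags + 1L
                tagno[v] <<- ntags
                sub <- rec(ch[[v]][1L])
                return(paste0("(", sub, ")#H", tagno[v]))
            }
            return(paste0("#H", tagno[v]))
        }
        kids <- ch[[v]]
        kids <- kids[order(vapply(kids, rec_min, integer(1)))]
        paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    }
    top <- ch[[net$n + 1L]][1L]
    paste0(rec(top), ";")
}

#' Parse an extended Newick string into a network
#'
#' Accepts the `#H` convention written by [write_enewick()]: every tag must
#' appear exactly twice, exactly once carrying a subtree. Leaf labels must
#' be 1..n; the graph must have the degree structure of a binary
#' phylogenetic network (tree vertices in 1 / out 2, reticulations in 2 /
#' out 1, a root above an ancestral root edge). Plain Newick (no tags)
#' parses to the k = 0 network.
#'
#' @param text An eNewick string.
#' @return An `arcnets_network`.
#' @export
read_enewick <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    p <- .parse_newick_nodes(text, allow_htags = TRUE)
    nodes <- p$nodes
    htags <- vapply(nodes, function(nd) nd$htag, integer(1))
    labels <- vapply(nodes, function(nd) nd$label, integer(1))
    for (tg in unique(htags[!is.na(htags)])) {
        occ <- which(htags == tg)
        if (length(occ) != 2L)
            stop("eNewick parse error: tag #H", tg, " occurs ", length(occ),
                 " times (expected 2)")
        carriers <- occ[vapply(occ, function(i) length(nodes[[i]]$children) > 0L, logical(1))]
        if (length(carriers) != 1L)
            stop("eNewick parse error: tag #H", tg,
                 " must carry a subtree in exactly one occurrence")
    }
    leaves <- which(!is.na(labels))
    n <- length(leaves)
    if (!setequal(labels[leaves], seq_len(n)))
        stop("eNewick parse error: leaf labels must be exactly 1..", n)
    # graph vertices: every node except bare tag occurrences (merged into
    # the carrier of the same tag)
    carrier_of <- function(tg) {
        occ <- which(htags == tg)
        occ[vapply(occ, function(i) length(nodes[[i]]$children) > 0L, logical(1))]
    }
    id <- integer(length(nodes))
    nxt <- n + 1L
    for (i in seq_along(nodes)) {
        if (!is.na(labels[i])) { id[i] <- labels[i]; next }
        if (!is.na(htags[i]) && length(nodes[[i]]$children) == 0L) next # bare ref
        nxt <- nxt + 1L
        id[i] <- nxt
    }
    for (i in seq_along(nodes))
        if (!is.na(htags[i]) && length(nodes[[i]]$children) == 0L)
            id[i] <- id[carrier_of(htags[i])]
    nv <- nxt
    edges <- matrix(integer(), 0L, 2L)
    for (i in seq_along(nodes))
        for (c in nodes[[i]]$children)
            edges <- rbind(edges, c(id[i], id[c]))
    edges <- rbind(c(n + 1L, id[p$top]), edges)
    ind <- .indeg(edges, nv)
    outd <- .outdeg(edges, nv)
    for (v in seq_len(nv)) {
        deg <- c(ind[v], outd[v])
        ok <- (v <= n && identical(deg, c(1L, 0L))) ||            # leaf
              (v == n + 1L && identical(deg, c(0L, 1L))) ||       # root
              (v > n + 1L && identical(deg, c(1L, 2L))) ||        # tree vertex
              (v > n + 1L && identical(deg, c(2L, 1L)))           # reticulation
        if (!ok)
            stop("eNewick parse error: vertex with in-degree ", ind[v],
                 " and out-degree ", outd[v],
                 " is not valid in a binary phylogenetic network")
    }
    new_network(n, nv, edges)
}
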