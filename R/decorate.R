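# The k-fold decoration process: sequentially subdivide edges of a tree with
# k ordered pairs of points (p_i, p'_i). Subdivision vertex ids extend the
# tree numbering: pair i has source 2n+2i-1 and target 2n+2i, so a decorated
# tree on [n] with k pairs has nv = 2n+2k vertices and 2n-1+2k tree edges.

new_decoration <- function(base, tk_edges, pairs) {
    k <- nrow(pairs)
    structure(list(base = base, n = base$n, k = as.integer(k),
                   nv = 2L * base$n + 2L * k,
                   tk_edges = .edge_matrix(tk_edges),
                   pairs = .edge_matrix(pairs)),
              class = "arcnets_decoration")
}

#' Number of k-fold decorations of a tree on n leaves
#'
#' A tree with an ancestral root edge has 2n-1 edges, so there are 2n-1
#' choices for the first point, 2n for its partner, and so on; dividing the
#' product (2n-1)(2n)...(2n+2k-2) by k! accounts for the k! insertion orders
#' of the pairs that produce the same decorated tree.
#'
#' @param n Leaf count (n >= 1).
#' @param k Number of arc pairs (k >= 0); `k = 0` gives 1.
#' @param log If `TRUE`, return the natural logarithm.
#' @return Exact count (decimal string when beyond 2^53).
#' @examples
#' count_decorations(4, 1)  # 56
#' count_decorations(4, 2)  # 2520
#' @export
count_decorations <- function(n, k, log = FALSE) {
    n <- .check_count(n, "n")
    k <- .check_count(k, "k", min = 0L)
    v <- cpp_count_decorations(n, k)
    if (log) return(v$log)
    .big_to_num(v$str)
}

#' Enumerate all k-fold decorations of a tree
#'
#' Generates every placement sequence (p_i on any edge of the current
#' subdivided tree, then p'_i on any edge of the result, including the two
#' half-edges just created) and deduplicates by the canonical decoration
#' code, under which each decorated tree is reached by exactly k! sequences.
#' No placement is forbidden at decoration time; structures that fail to be
#' networks are rejected later by classification.
#'
#' @param tree An `arcnets_tree`.
#' @param k Number of arc pairs (small: the raw sequence count is
#'   (2n-1)(2n)...(2n+2k-2)).
#' @return A list of `arcnets_decoration` objects, one per distinct decorated
#'   tree, with attribute `raw_sequences` giving the number of generated
#'   placement sequences (their ratio is k!).
#' @export
enumerate_decorations <- function(tree, k) {
    stopifnot(inherits(tree, "arcnets_tree"))
    k <- .check_count(k, "k", min = 0L)
    if (k > 2L || tree$n > 6L)
        stop("exhaustive decoration enumeration is supported for n <= 6, k <= 2")
    res <- cpp_enumerate_decorations(tree$edges, tree$n, k)
    out <- lapply(res$decorations, function(d)
        new_decoration(tree, d$tk_edges, d$pairs))
    attr(out, "raw_sequences") <- res$raw_sequences
    out
}

#' Sample a uniform k-fold decoration of a tree
#'
#' Each point is placed uniformly over the edges of the current subdivided
#' tree, in sequence. Every decorated tree arises from exactly k! placement
#' sequences, so the sampler is uniform over the decorated trees of `tree`.
#'
#' @param tree An `arcnets_tree`.
#' @param k Number of arc pairs.
#' @param seed Optional integer seed ([set.seed()] is called when given).
#' @return An `arcnets_decoration`.
#' @export
random_decoration <- function(tree, k, seed = NULL) {
    stopifnot(inherits(tree, "arcnets_tree"))
    k <- .check_count(k, "k", min = 0L)
    if (!is.null(seed)) set.seed(seed)
    res <- cpp_random_decoration(tree$edges, tree$n, k)
    new_decoration(tree, res$tk_edges, res$pairs)
}

#' Canonical code of a decorated tree
#'
#' A string equal for two decorated trees exactly when they are the same
#' decoration (label-preserving isomorphism of the subdivided tree carrying
#' the arc pairing as an unordered set of source -> target pairs). Used for
#' deduplication and for identifying sampled decorations.
#'
#' @param decoration An `arcnets_decoration`.
#' @return A character scalar.
#' @export
decoration_code <- function(decoration) {
    stopifnot(inherits(decoration, "arcnets_decoration"))
    cpp_decoration_code(decoration$tk_edges, decoration$pairs,
                        decoration$nv, decoration$n)
}

#' Induced subdivision tree of a decorated tree
#'
#' The minimal subtree of the subdivided tree containing all 2k subdivision
#' vertices, with pass-through binary vertices of the base tree suppressed:
#' its vertices are the subdivision vertices together with the branch points.
#' Every leaf of this subtree is a subdivision vertex; `ell` counts the
#' subdivision vertices that are not leaves of it (a unary root included),
#' and the subtree has 4k-2-ell edges.
#'
#' @param decoration An `arcnets_decoration` with k >= 1.
#' @return An object of class `arcnets_subtree` with fields `vertices`
#'   (topology vertex ids), `edges` (two-column matrix over those ids),
#'   `root`, `ell`, and `n_edges`.
#' @export
induced_subdivision_tree <- function(decoration) {
    stopifnot(inherits(decoration, "arcnets_decoration"))
    n <- decoration$n; k <- decoration$k; nv <- decoration$nv
    if (k < 1L) stop("the induced subdivision tree is undefined for k = 0")
    edges <- decoration$tk_edges
    marked <- 2L * n + seq_len(2L * k)
    ch <- .children(edges, nv)
    par <- .parent_vec(edges, nv)
    cnt <- integer(nv)
    # bottom-up subtree counts of marked vertices (postorder via sorting by
    # depth would do; recursion is fine at these sizes)
    rec <- function(v) {
        c0 <- if (v %in% marked) 1L else 0L
        for (w in ch[[v]]) c0 <- c0 + rec(w)
        cnt[v] <<- c0
        c0
    }
    total <- rec(n + 1L)
    stopifnot(total == 2L * k)
    # deepest vertex covering all marked vertices
    rstar <- n + 1L
    repeat {
        nxt <- ch[[rstar]][cnt[ch[[rstar]]] == total]
        if (length(nxt) == 0L) break
        rstar <- nxt[1L]
    }
    in_steiner <- (cnt >= 1L & cnt <= total - 1L)
    in_steiner[rstar] <- TRUE
    branch <- vapply(seq_len(nv), function(v) {
        if (!in_steiner[v] || v %in% marked) return(FALSE)
        sum(cnt[ch[[v]]] >= 1L) >= 2L
    }, logical(1))
    tverts <- sort(unique(c(marked, which(branch))))
    # connect each non-root topology vertex to its nearest topology ancestor
    tedges <- matrix(integer(), 0L, 2L)
    for (v in setdiff(tverts, rstar)) {
        u <- par[v]
        while (!(u %in% tverts)) u <- par[u]
        tedges <- rbind(tedges, c(u, v))
    }
    ell <- sum(cnt[marked] >= 2L)
    structure(list(vertices = tverts, edges = tedges, root = rstar,
                   ell = ell, n_edges = nrow(tedges), k = k),
              class = "arcnets_subtree")
}

# textual dump of a decorated tree: Newick of T_k with inline tags
# [pN:src] / [pN:tgt] on the subdivision vertices
format_decoration <- function(decoration) {
    d <- decoration
    ch <- .children(d$tk_edges, d$nv)
    tag <- character(d$nv)
    for (i in seq_len(d$k)) {
        tag[d$pairs[i, 1L]] <- sprintf("[p%d:src]", i)
        tag[d$pairs[i, 2L]] <- sprintf("[p%d:tgt]", i)
    }
    rec_min <- function(v) {
        if (v <= d$n) return(v)
        min(vapply(ch[[v]], rec_min, integer(1)))
    }
    rec <- function(v) {
        kids <- ch[[v]]
        if (length(kids) == 0L) return(as.character(v))
        if (length(kids) == 1L) return(paste0(rec(kids[1L]), tag[v]))
        kids <- kids[order(vapply(kids, rec_min, integer(1)))]
        paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    }
    top <- ch[[d$n + 1L]][1L]
    paste0(rec(top), ";")
}

#' @export
print.arcnets_decoration <- function(x, ...) {
    cat(sprintf("%d-fold decorated tree on [%d] (%d vertices)\n", x$k, x$n, x$nv))
    cat(format_decoration(x), "\n")
    invisible(x)
}

#' @export
print.arcnets_subtree <- function(x, ...) {
    cat(sprintf("Induced subdivision tree: %d vertices, %d edges, ell = %d (4k-2-ell = %d)\n",
                length(x$vertices), x$n_edges, x$ell, 4L * x$k - 2L - x$ell))
    invisible(x)
}
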