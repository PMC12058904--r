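# The candidate network G((T_k, omega_k)): the subdivided tree plus one arc
# p_i -> p'_i per pair. Each arc source becomes a tree vertex (in 1, out 2)
# and each arc target a reticulation vertex (in 2, out 1). The graph is a
# multigraph: an arc parallel to the tree edge between its endpoints is legal
# and classified as a shortcut.

new_network <- function(n, nv, edges, k = NULL) {
    edges <- .edge_matrix(edges)
    if (is.null(k)) {
        ind <- .indeg(edges, nv)
        k <- sum(ind >= 2L)
    }
    structure(list(n = as.integer(n), nv = as.integer(nv), edges = edges,
                   k = as.integer(k)),
              class = "arcnets_network")
}

#' Build the directed graph of a decorated tree
#'
#' Adds one arc p_i -> p'_i per pair to the subdivided tree. The result may
#' contain directed cycles, in which case it is not a phylogenetic network.
#'
#' @param x An `arcnets_decoration` (or an `arcnets_tree`, giving the k = 0
#'   graph, i.e. the tree itself).
#' @return An `arcnets_network`.
#' @export
as_network <- function(x) {
    if (inherits(x, "arcnets_network")) return(x)
    if (inherits(x, "arcnets_tree"))
        return(new_network(x$n, x$nv, x$edges, k = 0L))
    stopifnot(inherits(x, "arcnets_decoration"))
    new_network(x$n, x$nv, rbind(x$tk_edges, x$pairs), k = x$k)
}

.classify_raw <- function(net, want_dates = FALSE) {
    cpp_classify(net$edges, net$nv, want_dates)
}

.stop_if_cyclic <- function(net, what) {
    if (!.classify_raw(net)$acyclic)
        stop(what, " is undefined for a cyclic graph", call. = FALSE)
}

#' Classify a candidate network
#'
#' Assigns exactly one of five mutually exclusive labels:
#' \describe{
#'   \item{`cyclic`}{the graph has a directed cycle (not a network);}
#'   \item{`not_tree_child`}{a network, but some non-leaf vertex has only
#'     reticulation children;}
#'   \item{`shortcut`}{tree-child, but some edge (u,v) admits another
#'     directed path from u to v (parallel arcs included);}
#'   \item{`normal_not_hyb`}{normal (tree-child, no shortcut) but with no
#'     temporal ranking;}
#'   \item{`hybridization`}{normal and temporally rankable.}
#' }
#' The coarse classes are recovered by [coarse_class()]: `cyclic` forms
#' S_c, `not_tree_child`/`shortcut` form the non-normal networks, and the
#' last two labels form the normal networks.
#'
#' @param x An `arcnets_network`, `arcnets_decoration`, or `arcnets_tree`.
#' @return A character scalar, one of the five labels above.
#' @export
classify_network <- function(x) {
    .classify_raw(as_network(x))$label
}

#' @rdname classify_network
#' @param label A fine label as returned by [classify_network()].
#' @export
coarse_class <- function(label) {
    stopifnot(is.character(label))
    out <- ifelse(label == "cyclic", "cyclic",
           ifelse(label %in% c("not_tree_child", "shortcut"), "non_normal_network",
           ifelse(label %in% c("normal_not_hyb", "hybridization"), "normal",
                  NA_character_)))
    if (anyNA(out)) stop("unknown class label")
    out
}

#' Acyclicity, tree-child and shortcut tests
#'
#' `is_acyclic` tests for the absence of directed cycles (an acyclic
#' decoration graph is a phylogenetic network). `is_tree_child` tests that
#' every non-leaf vertex has at least one child that is a leaf or a tree
#' vertex. `shortcuts` returns every edge (u,v) for which another directed
#' path from u to v exists; a network is normal exactly when it is
#' tree-child with no shortcut. The latter two require an acyclic graph.
#'
#' @param x An `arcnets_network` (or coercible via [as_network()]).
#' @return `is_acyclic`/`is_tree_child`: a logical scalar. `shortcuts`: a
#'   two-column matrix of shortcut edges (zero rows when none).
#' @export
is_acyclic <- function(x) {
    .classify_raw(as_network(x))$acyclic
}

#' @rdname is_acyclic
#' @export
is_tree_child <- function(x) {
    net <- as_network(x)
    .stop_if_cyclic(net, "the tree-child condition")
    .classify_raw(net)$tree_child
}

#' @rdname is_acyclic
#' @export
shortcuts <- function(x) {
    net <- as_network(x)
    .stop_if_cyclic(net, "shortcut detection")
    idx <- .classify_raw(net)$shortcut_edges
    net$edges[idx, , drop = FALSE]
}

#' @rdname is_acyclic
#' @export
is_normal <- function(x) {
    net <- as_network(x)
    .stop_if_cyclic(net, "normality")
    cl <- .classify_raw(net)
    cl$tree_child && !cl$has_shortcut
}

#' Temporal ranking of a network
#'
#' A hybridization (temporal) network admits dates T(v) with T(u) < T(v)
#' along every tree edge and T(u) = T(v) = T(w) for every reticulation
#' vertex v with parents u and w. Each reticulation is merged with its two
#' parents into an equivalence class; a ranking exists iff no tree edge
#' joins two vertices of one class and the quotient digraph is acyclic.
#' Dates are integers 0..m-1, constant on classes, assigned deterministically
#' (classes become available in Kahn order, ties broken by smallest member).
#'
#' @param x An `arcnets_network` (or coercible). Must be acyclic.
#' @return An integer vector of dates indexed by vertex id, or `NULL` when
#'   no temporal ranking exists.
#' @seealso [validate_temporal_ranking()] for the literal condition check.
#' @export
temporal_ranking <- function(x) {
    net <- as_network(x)
    .stop_if_cyclic(net, "temporal ranking")
    cl <- .classify_raw(net, want_dates = TRUE)
    if (!cl$temporal_ok) return(NULL)
    dates <- cl$dates
    names(dates) <- seq_len(net$nv)
    dates
}

#' Literal re-check of a temporal ranking
#'
#' Verifies, edge by edge and independently of the ranking construction,
#' that `dates` satisfies (i) strict increase along every tree edge and
#' (ii) equality across every reticulation vertex and its two parents.
#'
#' @param x An `arcnets_network` (or coercible).
#' @param dates Integer dates per vertex, as from [temporal_ranking()].
#' @return `TRUE` or `FALSE`.
#' @export
validate_temporal_ranking <- function(x, dates) {
    net <- as_network(x)
    stopifnot(length(dates) == net$nv)
    ind <- .indeg(net$edges, net$nv)
    for (e in seq_len(nrow(net$edges))) {
        u <- net$edges[e, 1L]; v <- net$edges[e, 2L]
        if (ind[v] <= 1L) {
            if (!(dates[u] < dates[v])) return(FALSE)   # (i) tree edge
        } else {
            if (dates[u] != dates[v]) return(FALSE)     # (ii) reticulation
        }
    }
    TRUE
}

#' Collinear pairs of reticulation edges
#'
#' Two reticulation edges with distinct head reticulation vertices are
#' collinear when an endpoint of one is connected to an endpoint of the
#' other by a directed path consisting only of tree edges (the empty path
#' counts, so sharing a vertex qualifies). For a normal network with no
#' collinear pair, a temporal ranking always exists; the pairs with the same
#' head (the two edges into one reticulation) are excluded by convention.
#'
#' @param x An `arcnets_network` (or coercible). Must be acyclic.
#' @return A two-column matrix of row indices into the edge matrix, one row
#'   per unordered collinear pair (zero rows when none).
#' @export
collinear_pairs <- function(x) {
    net <- as_network(x)
    .stop_if_cyclic(net, "collinearity")
    nv <- net$nv
    ind <- .indeg(net$edges, nv)
    retic_e <- which(ind[net$edges[, 2L]] >= 2L)
    out <- matrix(integer(), 0L, 2L)
    if (length(retic_e) < 2L) return(out)
    # reflexive-transitive closure over tree edges only
    reach <- diag(nv) > 0
    A <- matrix(FALSE, nv, nv)
    for (e in seq_len(nrow(net$edges)))
        if (ind[net$edges[e, 2L]] <= 1L)
            A[net$edges[e, 1L], net$edges[e, 2L]] <- TRUE
    repeat {
        nxt <- reach | (reach %*% A > 0)
        if (identical(nxt, reach)) break
        reach <- nxt
    }
    for (a in seq_along(retic_e)) {
        for (b in seq_len(a - 1L)) {
            ea <- retic_e[a]; eb <- retic_e[b]
            if (net$edges[ea, 2L] == net$edges[eb, 2L]) next # same head
            va <- net$edges[ea, ]; vb <- net$edges[eb, ]
            hit <- FALSE
            for (u in va) for (w in vb)
                if (reach[u, w] || reach[w, u]) hit <- TRUE
            if (hit) out <- rbind(out, c(eb, ea))
        }
    }
    out
}

#' Displayed trees of a normal network
#'
#' For each reticulation vertex, one of the two incoming arcs is deleted and
#' the resulting degree-2 vertices are suppressed (iterated until none
#' remain); ranging over all 2^k deletion choices yields the displayed
#' trees. A normal network with k reticulations displays exactly 2^k
#' distinct trees.
#'
#' @param x An `arcnets_network` (or coercible). Must be a normal network.
#' @return A list of distinct `arcnets_tree` objects.
#' @export
displayed_trees <- function(x) {
    net <- as_network(x)
    if (!is_normal(net)) stop("displayed trees are only defined here for normal networks")
    n <- net$n
    ind <- .indeg(net$edges, net$nv)
    retics <- which(ind >= 2L)
    k <- length(retics)
    in_edges <- lapply(retics, function(v) which(net$edges[, 2L] == v))
    seen <- character()
    out <- list()
    choices <- if (k == 0L) matrix(integer(), 1L, 0L)
               else as.matrix(expand.grid(rep(list(1:2), k)))
    for (r in seq_len(nrow(choices))) {
        drop <- vapply(seq_len(k), function(i) in_edges[[i]][choices[r, i]], integer(1))
        edges <- net$edges[setdiff(seq_len(nrow(net$edges)), drop), , drop = FALSE]
        tr <- .suppress_to_tree(edges, n, net$nv)
        code <- cpp_canonical_code(tr$edges, tr$nv, n, TRUE)
        if (!(code %in% seen)) {
            seen <- c(seen, code)
            out[[length(out) + 1L]] <- tr
        }
    }
    out
}

# delete-and-suppress helper: repeatedly contract in-1/out-1 vertices, then
# renumber internal vertices to the tree convention (leaves 1..n, root n+1)
.suppress_to_tree <- function(edges, n, nv) {
    repeat {
        ind <- .indeg(edges, nv)
        outd <- .outdeg(edges, nv)
        mid <- which(ind == 1L & outd == 1L)
        if (length(mid) == 0L) break
        v <- mid[1L]
        e_in <- which(edges[, 2L] == v)
        e_out <- which(edges[, 1L] == v)
        edges[e_in, 2L] <- edges[e_out, 2L]
        edges <- edges[-e_out, , drop = FALSE]
    }
    verts <- sort(unique(as.integer(edges)))
    stopifnot(all(seq_len(n) %in% verts), (n + 1L) %in% verts)
    internal <- setdiff(verts, c(seq_len(n), n + 1L))
    map <- integer(max(verts))
    map[seq_len(n)] <- seq_len(n)
    map[n + 1L] <- n + 1L
    map[internal] <- n + 1L + seq_along(internal)
    new_phylo_tree(n, cbind(map[edges[, 1L]], map[edges[, 2L]]))
}

#' Canonical code of a network
#'
#' A string such that two acyclic graphs receive the same code exactly when
#' a directed-graph isomorphism between them maps leaf i to leaf i (or, with
#' `labeled = FALSE`, when they are isomorphic with leaf labels erased --
#' the "shape" equivalence). Computed by colour refinement with explicit
#' individualization backtracking, taking the minimum over all branches, so
#' equality certifies isomorphism.
#'
#' @param x An `arcnets_network`, `arcnets_decoration`, or `arcnets_tree`.
#' @param labeled Keep leaf labels distinct (default) or erase them.
#' @return A character scalar.
#' @export
canonical_code <- function(x, labeled = TRUE) {
    net <- as_network(x)
    .stop_if_cyclic(net, "the canonical code")
    cpp_canonical_code(net$edges, net$nv, net$n, labeled)
}

#' @export
print.arcnets_network <- function(x, ...) {
    cl <- .classify_raw(x)
    cat(sprintf("Candidate phylogenetic network: n = %d leaves, %d reticulation vertices\n",
                x$n, x$k))
    if (cl$acyclic) {
        cat("class:", cl$label, "\n")
        cat(write_enewick(x), "\n")
    } else {
        cat("class: cyclic (contains a directed cycle; not a network)\n")
    }
    invisible(x)
}
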