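# Rooted binary phylogenetic trees on leaf set 1..n with an ancestral root
# edge. Vertex numbering convention (shared with the compiled core):
#   1..n    leaves, leaf i carries label i
#   n+1     root: in-degree 0, out-degree 1 (top of the ancestral root edge)
#   n+2..2n internal tree vertices
# A tree has 2n-1 edges including the root edge.

new_phylo_tree <- function(n, edges) {
    structure(list(n = as.integer(n), nv = 2L * as.integer(n),
                   edges = .edge_matrix(edges)),
              class = "arcnets_tree")
}

#' Number of rooted binary phylogenetic trees on n leaves
#'
#' Counts trees in which each leaf carries a distinct label from 1..n, every
#' internal vertex is binary, and an ancestral root edge hangs above the top
#' tree vertex. The count is the semifactorial (2n-3)!!, evaluated exactly
#' through the factorial identity (2n-2)! / (2^(n-1) (n-1)!).
#'
#' @param n Number of leaves (a single integer, n >= 1).
#' @param log If `TRUE`, return the natural logarithm of the count instead.
#' @return The exact count. Values that exceed the exactly representable
#'   double range (2^53) are returned as a decimal character string.
#' @examples
#' count_trees(4)  # 15
#' count_trees(6)  # 945
#' @export
count_trees <- function(n, log = FALSE) {
    n <- .check_count(n, "n")
    v <- cpp_count_trees(n)
    if (log) return(v$log)
    .big_to_num(v$str)
}

#' Enumerate all rooted binary phylogenetic trees on n leaves
#'
#' Generates every tree exactly once by sequential leaf insertion: the tree on
#' leaf 1 is a single leaf below the root edge, and leaf j+1 is attached by
#' subdividing any of the 2j-1 edges of the current tree. Each labeled tree
#' arises from exactly one insertion sequence, so no deduplication is needed.
#'
#' @param n Number of leaves; enumeration is intended for n <= 8
#'   ((2n-3)!! grows fast: n = 8 gives 135135 trees).
#' @return A list of `arcnets_tree` objects of length `count_trees(n)`.
#' @export
enumerate_trees <- function(n) {
    n <- .check_count(n, "n")
    if (n > 8L) stop("exhaustive tree enumeration is supported for n <= 8 (",
                     cpp_count_trees(n)$str, " trees requested)")
    lapply(cpp_enumerate_trees(n), function(e) new_phylo_tree(n, e))
}

#' Sample a rooted binary phylogenetic tree uniformly at random
#'
#' Leaf j+1 is attached to an edge chosen uniformly among the 2j-1 edges of
#' the current tree, which makes the sampler exactly uniform over the
#' (2n-3)!! trees. Reproducible through R's RNG: an explicit `seed` calls
#' [set.seed()] first.
#'
#' @param n Number of leaves.
#' @param seed Optional integer seed.
#' @return An `arcnets_tree`.
#' @export
random_tree <- function(n, seed = NULL) {
    n <- .check_count(n, "n")
    if (!is.null(seed)) set.seed(seed)
    new_phylo_tree(n, cpp_random_tree(n))
}

# ------------------------------------------------------------------ Newick

# recursive-descent parser used for both plain Newick and extended Newick.
# Returns a list of nodes: list(children = integer vector of node ids,
# label = integer or NA, htag = integer or NA); node 1 is the top subtree.
.parse_newick_nodes <- function(text, allow_htags = FALSE) {
    s <- gsub("[[:space:]]", "", text)
    pos <- 1L
    nodes <- list()
    err <- function(msg) stop(sprintf("Newick parse error at position %d: %s", pos, msg),
                              call. = FALSE)
    peek <- function() if (pos <= nchar(s)) substr(s, pos, pos) else ""
    advance <- function() pos <<- pos + 1L
    read_int <- function() {
        m <- regmatches(substr(s, pos, nchar(s)),
                        regexpr("^[0-9]+", substr(s, pos, nchar(s))))
        if (length(m) == 0L) err("expected an integer label")
        pos <<- pos + nchar(m)
        as.integer(m)
    }
    new_node <- function() {
        nodes[[length(nodes) + 1L]] <<- list(children = integer(), label = NA_integer_,
                                             htag = NA_integer_)
        length(nodes)
    }
    parse_subtree <- function() {
        id <- new_node()
        ch <- peek()
        if (ch == "(") {
            advance()
            repeat {
                cid <- parse_subtree()
                nodes[[id]]$children <<- c(nodes[[id]]$children, cid)
                if (peek() == ",") { advance(); next }
                if (peek() == ")") { advance(); break }
                err("expected ',' or ')'")
            }
            if (peek() == "#") {
                if (!allow_htags) err("'#' tags are not valid in plain Newick")
                advance()
                if (peek() != "H") err("expected 'H' after '#'")
                advance()
                nodes[[id]]$htag <<- read_int()
            }
        } else if (ch == "#") {
            if (!allow_htags) err("'#' tags are not valid in plain Newick")
            advance()
            if (peek() != "H") err("expected 'H' after '#'")
            advance()
            nodes[[id]]$htag <<- read_int()
        } else if (grepl("^[0-9]$", ch)) {
            nodes[[id]]$label <<- read_int()
        } else {
            err(sprintf("unexpected character '%s'", ch))
        }
        id
    }
    top <- parse_subtree()
    if (peek() != ";") err("expected ';'")
    advance()
    if (pos <= nchar(s)) err("trailing characters after ';'")
    list(nodes = nodes, top = top)
}

#' Parse a rooted binary tree from a Newick string
#'
#' The dialect is minimal: leaf labels are the integers 1..n, there are no
#' branch lengths, internal vertices are unlabeled, and the string ends with
#' a semicolon. The ancestral root edge is implicit in serialization and is
#' re-added on parsing. Malformed input, non-binary vertices, and duplicate
#' or missing labels raise an error that reports the offending position.
#'
#' @param text A Newick string such as `"((1,2),(3,4));"`.
#' @return An `arcnets_tree`.
#' @seealso [write_newick()]
#' @export
read_newick <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    p <- .parse_newick_nodes(text, allow_htags = FALSE)
    nodes <- p$nodes
    labels <- vapply(nodes, function(nd) nd$label, integer(1))
    leaves <- which(!is.na(labels))
    n <- length(leaves)
    if (n == 0L) stop("Newick parse error: no leaves found")
    if (!setequal(labels[leaves], seq_len(n)))
        stop("Newick parse error: leaf labels must be exactly 1..", n,
             " (got ", paste(sort(labels[leaves]), collapse = ","), ")")
    for (nd in nodes) {
        if (is.na(nd$label) && length(nd$children) != 2L)
            stop("Newick parse error: internal vertices must have exactly 2 children")
    }
    # vertex ids: leaves by label, root n+1, internals n+2..
    id <- integer(length(nodes))
    nxt <- n + 1L
    for (i in seq_along(nodes)) {
        if (!is.na(nodes[[i]]$label)) id[i] <- nodes[[i]]$label
        else { nxt <- nxt + 1L; id[i] <- nxt }
    }
    edges <- matrix(integer(), 0L, 2L)
    for (i in seq_along(nodes))
        for (c in nodes[[i]]$children)
            edges <- rbind(edges, c(id[i], id[c]))
    edges <- rbind(c(n + 1L, id[p$top]), edges) # ancestral root edge
    new_phylo_tree(n, edges)
}

#' Serialize a tree as a Newick string
#'
#' Children are ordered by the smallest leaf label in their subtree, so the
#' output is a deterministic function of the tree (not of its construction
#' history). The ancestral root edge is implicit.
#'
#' @param tree An `arcnets_tree`.
#' @return A single Newick string.
#' @export
write_newick <- function(tree) {
    stopifnot(inherits(tree, "arcnets_tree"))
    ch <- .children(tree$edges, tree$nv)
    minleaf <- integer(tree$nv)
    rec_min <- function(v) {
        if (v <= tree$n) return(v)
        m <- min(vapply(ch[[v]], rec_min, integer(1)))
        m
    }
    rec <- function(v) {
        if (v <= tree$n) return(as.character(v))
        kids <- ch[[v]]
        kids <- kids[order(vapply(kids, rec_min, integer(1)))]
        paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    }
    top <- ch[[tree$n + 1L]][1L]
    paste0(rec(top), ";")
}

#' @export
print.arcnets_tree <- function(x, ...) {
    cat("Rooted binary phylogenetic tree on", x$n,
        if (x$n == 1L) "leaf" else "leaves",
        "(", nrow(x$edges), "edges incl. root edge )\n")
    cat(write_newick(x), "\n")
    invisible(x)
}
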