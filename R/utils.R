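# internal helpers shared across modules

# decimal string -> numeric when exactly representable in a double,
# otherwise the string itself (documented behaviour of the exact formulas)
.big_to_num <- function(str) {
    v <- suppressWarnings(as.numeric(str))
    if (!is.na(v) && abs(v) < 2^53) return(v)
    str
}

.check_count <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
        stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
    as.integer(x)
}

# in-degrees / out-degrees over vertices 1..nv from an edge matrix
.indeg <- function(edges, nv) tabulate(edges[, 2L], nbins = nv)
.outdeg <- function(edges, nv) tabulate(edges[, 1L], nbins = nv)

# children list indexed by parent vertex
.children <- function(edges, nv) {
    ch <- vector("list", nv)
    for (e in seq_len(nrow(edges))) ch[[edges[e, 1L]]] <- c(ch[[edges[e, 1L]]], edges[e, 2L])
    ch
}

# parent vector for a tree edge matrix (NA for the root)
.parent_vec <- function(edges, nv) {
    p <- rep(NA_integer_, nv)
    p[edges[, 2L]] <- edges[, 1L]
    p
}

.edge_matrix <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (ncol(m) != 2L) stop("edge matrix must have two columns (parent, child)")
    m
}
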