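# Exhaustive census: iterate every k-fold decorated tree on [n], classify
# the resulting graph, stratify by the induced subdivision tree, and
# deduplicate the normal outcomes by canonical code.

.census_supported <- function(n, k) {
    (k == 0L && n <= 8L) || (k == 1L && n <= 6L) || (k == 2L && n <= 5L)
}

#' Exhaustive census of k-fold decorated trees on [n]
#'
#' Enumerates all decorated trees (every tree on leaf set 1..n crossed with
#' every placement of k point pairs), classifies each resulting graph, and
#' deduplicates the normal outcomes by label-preserving canonical code. The
#' census streams over placement sequences in compiled code and retains only
#' the canonical codes of normal outcomes, so memory stays proportional to
#' the number of distinct normal networks, not to the number of decorated
#' trees.
#'
#' @param n Leaf count.
#' @param k Number of arc pairs. Supported exhaustive range: `n <= 8` for
#'   `k = 0`, `n <= 6` for `k = 1`, `n <= 5` for `k = 2`; anything larger is
#'   refused with a size estimate.
#' @param shapes Also group the distinct normal networks by unlabeled
#'   isomorphism and record the orbit sizes.
#' @param reps Also return one representative `arcnets_network` per distinct
#'   normal network.
#' @return An object of class `arcnets_census`: a list with the total count,
#'   per-class counts (`cyclic`, `not_tree_child`, `shortcut`,
#'   `normal_not_hyb`, `hybridization`), coarse counts (`S_c`, `S_not_no`,
#'   `S_no`, `S_hyb`), counts stratified by the number `ell` of non-leaf
#'   subdivision vertices, the deduplicated counts `distinct_normal`
#'   (N_{n,k}) and `distinct_hyb` (H_{n,k}), and optionally `shape_sizes`
#'   and `reps`/`rep_is_hyb`.
#' @examples
#' cs <- run_census(4, 1)
#' cs$distinct_normal  # 54
#' @export
run_census <- function(n, k, shapes = FALSE, reps = FALSE) {
    n <- .check_count(n, "n")
    k <- .check_count(k, "k", min = 0L)
    if (!.census_supported(n, k)) {
        sz <- cpp_S_total(n, k)$str
        stop("exhaustive census refused for (n = ", n, ", k = ", k, "): ",
             sz, " decorated trees; supported range is n <= 8 (k = 0), ",
             "n <= 6 (k = 1), n <= 5 (k = 2)", call. = FALSE)
    }
    res <- cpp_census(n, k, shapes, reps)
    counts <- res$counts
    S_no <- unname(counts["normal_not_hyb"] + counts["hybridization"])
    S_hyb <- unname(counts["hybridization"])
    # structural invariants of the census, checked on every run
    total_expected <- cpp_S_total(n, k)$str
    if (res$total != as.numeric(total_expected))
        stop("census invariant violated: total != |S(n,k)|")
    if (S_no != 2^k * res$distinct_normal)
        stop("census invariant violated: |S_no| != 2^k * N")
    if (S_hyb != 2^k * res$distinct_hyb)
        stop("census invariant violated: |S_hyb| != 2^k * H")
    if (res$cyclic_ell0 != 0)
        stop("census invariant violated: cyclic decorated tree with ell = 0")
    by_ell <- res$by_ell
    if (k > 0L) names(by_ell) <- as.character(seq_len(2L * k) - 1L)
    out <- list(n = n, k = k,
                total = res$total,
                counts = counts,
                S_c = unname(counts["cyclic"]),
                S_not_no = unname(counts["not_tree_child"] + counts["shortcut"]),
                S_no = S_no, S_hyb = S_hyb,
                by_ell = by_ell,
                distinct_normal = res$distinct_normal,
                distinct_hyb = res$distinct_hyb)
    if (shapes) {
        out$shape_sizes <- res$shape_sizes
        if (sum(res$shape_sizes) != res$distinct_normal)
            stop("census invariant violated: shape orbit sizes do not sum to N")
    }
    if (reps) {
        nv <- 2L * n + 2L * k
        out$reps <- lapply(res$reps, function(e) new_network(n, nv, e, k = k))
        out$rep_is_hyb <- res$rep_is_hyb
    }
    class(out) <- "arcnets_census"
    out
}

#' Shape census: unlabeled orbit sizes of the normal networks
#'
#' Groups the distinct normal networks of [run_census()] by isomorphism
#' ignoring leaf labels and returns the orbit sizes, largest first.
#'
#' @inheritParams run_census
#' @return An integer vector of orbit sizes summing to `distinct_normal`.
#' @examples
#' shape_census(4, 2)  # 24 12 12: three shapes
#' @export
shape_census <- function(n, k) {
    run_census(n, k, shapes = TRUE)$shape_sizes
}

#' @export
print.arcnets_census <- function(x, ...) {
    cat(sprintf("Census of %d-fold decorated trees on [%d]: %s decorated trees\n",
                x$k, x$n, format(x$total, big.mark = ",")))
    tab <- data.frame(count = c(x$counts, S_no = x$S_no),
                      row.names = c(names(x$counts), "normal (S_no)"))
    print(tab)
    cat(sprintf("distinct normal networks N = %d, distinct hybridization networks H = %d\n",
                x$distinct_normal, x$distinct_hyb))
    if (!is.null(x$shape_sizes))
        cat("unlabeled shape orbit sizes:", paste(x$shape_sizes, collapse = ", "), "\n")
    if (x$k > 0L) {
        cat("by ell (non-leaf subdivision vertices):\n")
        print(x$by_ell)
    }
    invisible(x)
}
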