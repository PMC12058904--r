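# Seeded Monte Carlo estimation of class proportions at parameter values
# beyond exhaustive reach: uniform decorated trees via random_tree +
# random_decoration (batched in compiled code), classified one by one.

#' Wilson score interval for a binomial proportion
#'
#' Preferred over the Wald interval because the class proportions of
#' interest sit close to 0 or 1 at small and large n respectively.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(estimate, lower, upper)`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
    stopifnot(n >= 1, x >= 0, x <= n)
    z <- qnorm(1 - (1 - conf) / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Monte Carlo estimate of decoration-class proportions
#'
#' Draws M independent uniform k-fold decorated trees on [n] (uniform tree,
#' then uniform sequential point placement), classifies each, and reports
#' per-class proportions with Wilson score intervals. Also reports the
#' derived proportions P(network) (acyclic), P(normal), and
#' P(hybridization | normal).
#'
#' @param n Leaf count.
#' @param k Number of arc pairs.
#' @param M Number of samples.
#' @param seed Optional integer seed ([set.seed()] is called when given);
#'   identical seeds give identical reports.
#' @param conf Confidence level for the intervals.
#' @return An object of class `arcnets_propest`.
#' @examples
#' est <- estimate_proportions(4, 2, 2000, seed = 1)
#' est$p_normal
#' @export
estimate_proportions <- function(n, k, M, seed = NULL, conf = 0.95) {
    n <- .check_count(n, "n")
    k <- .check_count(k, "k", min = 0L)
    M <- .check_count(M, "M")
    if (!is.null(seed)) set.seed(seed)
    counts <- cpp_mc_classify(n, k, M)
    stopifnot(sum(counts) == M)
    per_class <- t(vapply(names(counts), function(cl)
        wilson_interval(counts[[cl]], M, conf), numeric(3)))
    n_normal <- unname(counts[["normal_not_hyb"]] + counts[["hybridization"]])
    out <- list(n = n, k = k, M = M, seed = seed, conf = conf,
                counts = counts,
                per_class = per_class,
                p_network = wilson_interval(M - counts[["cyclic"]], M, conf),
                p_normal = wilson_interval(n_normal, M, conf),
                p_hyb_given_normal = if (n_normal > 0)
                    wilson_interval(unname(counts[["hybridization"]]), n_normal, conf)
                else c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
    class(out) <- "arcnets_propest"
    out
}

#' Monte Carlo trend of P(normal) along a grid of n
#'
#' Runs [estimate_proportions()] at fixed k for each n in `n_grid` and
#' tabulates P(normal) and P(hybridization | normal) with their intervals.
#' As n grows with k fixed (or growing slower than n^(1/3)), the proportion
#' of arc placements that yield a normal network tends to 1; the estimated
#' column should be nondecreasing up to confidence-interval overlap.
#'
#' @param k Number of arc pairs.
#' @param n_grid Increasing vector of leaf counts.
#' @param M Samples per grid point.
#' @param seed Optional integer seed for the whole experiment (a single
#'   stream is consumed across the grid).
#' @param conf Confidence level.
#' @return A data frame with one row per grid point.
#' @export
trend_experiment <- function(k, n_grid, M, seed = NULL, conf = 0.95) {
    k <- .check_count(k, "k", min = 0L)
    stopifnot(is.numeric(n_grid), length(n_grid) >= 1L, !is.unsorted(n_grid))
    if (!is.null(seed)) set.seed(seed)
    rows <- lapply(n_grid, function(n) {
        est <- estimate_proportions(n, k, M, seed = NULL, conf = conf)
        data.frame(n = n, k = k, M = M,
                   p_normal = est$p_normal[["estimate"]],
                   normal_lower = est$p_normal[["lower"]],
                   normal_upper = est$p_normal[["upper"]],
                   p_hyb_given_normal = est$p_hyb_given_normal[["estimate"]],
                   hyb_lower = est$p_hyb_given_normal[["lower"]],
                   hyb_upper = est$p_hyb_given_normal[["upper"]])
    })
    do.call(rbind, rows)
}

#' @export
print.arcnets_propest <- function(x, ...) {
    cat(sprintf("Monte Carlo classification of %d uniform %d-fold decorated trees on [%d]\n",
                x$M, x$k, x$n))
    tab <- data.frame(count = as.integer(x$counts),
                      proportion = x$per_class[, "estimate"],
                      lower = x$per_class[, "lower"],
                      upper = x$per_class[, "upper"],
                      row.names = names(x$counts))
    print(tab, digits = 4)
    cat(sprintf("P(network) = %.4f [%.4f, %.4f]\n",
                x$p_network[["estimate"]], x$p_network[["lower"]], x$p_network[["upper"]]))
    cat(sprintf("P(normal)  = %.4f [%.4f, %.4f]\n",
                x$p_normal[["estimate"]], x$p_normal[["lower"]], x$p_normal[["upper"]]))
    if (!is.na(x$p_hyb_given_normal[["estimate"]]))
        cat(sprintf("P(hybridization | normal) = %.4f [%.4f, %.4f]\n",
                    x$p_hyb_given_normal[["estimate"]],
                    x$p_hyb_given_normal[["lower"]], x$p_hyb_given_normal[["upper"]]))
    invisible(x)
}
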