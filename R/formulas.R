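# Exact closed-form counts and asymptotic approximations for normal and
# hybridization networks with k = 1, 2 reticulations.

#' Exact count of hybridization networks with one reticulation
#'
#' For one reticulation the hybridization and normal counts coincide:
#' H(n,1) = N(n,1) = (1/2)((2n+1)!! + 3 (2n-1)!!) - 3 n! 2^(n-1), which is
#' n!/2 times the n-th coefficient of (r/(1-r))^3 with r = 1 - sqrt(1-2z).
#'
#' @param n Leaf count, n >= 3.
#' @param log Return the natural logarithm instead.
#' @return Exact count (decimal string when beyond 2^53).
#' @examples
#' H1_exact(4)  # 54
#' @export
H1_exact <- function(n, log = FALSE) {
    n <- .check_count(n, "n", min = 3L)
    v <- cpp_H1_exact(n)
    if (log) return(v$log)
    .big_to_num(v$str)
}

#' Exact count of hybridization networks with two reticulations
#'
#' H(n,2) = (2n-1)!! (n^3 + 9n^2 - 16n - 12) - 3 n! 2^n (n^2 - 4), obtained
#' from the bridgeless-component decomposition of the generating function
#' H_2(z) (see [H2_series()]).
#'
#' @param n Leaf count, n >= 4.
#' @param log Return the natural logarithm instead.
#' @return Exact count.
#' @examples
#' H2_exact(4)  # 36
#' H2_exact(6)  # 66960
#' @export
H2_exact <- function(n, log = FALSE) {
    n <- .check_count(n, "n", min = 4L)
    v <- cpp_H2_exact(n)
    if (log) return(v$log)
    .big_to_num(v$str)
}

#' Exact count of normal networks with two reticulations
#'
#' N(n,2) = (1/3)(2n-1)!!(3n-4)(n^2+11n+6) - n! 2^n (3n^2+2n-8); the
#' division by 3 is exact and asserted.
#'
#' @param n Leaf count, n >= 4.
#' @param log Return the natural logarithm instead.
#' @return Exact count.
#' @examples
#' N2_exact(4)  # 48
#' @export
N2_exact <- function(n, log = FALSE) {
    n <- .check_count(n, "n", min = 4L)
    v <- cpp_N2_exact(n)
    if (log) return(v$log)
    .big_to_num(v$str)
}

#' Exact difference N(n,2) - H(n,2)
#'
#' The number of normal networks with two reticulations that are not
#' hybridization networks; asymptotically (2 sqrt(2)/3) (2/e)^n n^(n+2).
#'
#' @param n Leaf count, n >= 4.
#' @param log Return the natural logarithm instead.
#' @return Exact count.
#' @export
NH2_diff_exact <- function(n, log = FALSE) {
    n <- .check_count(n, "n", min = 4L)
    v <- cpp_N2_minus_H2(n)
    if (log) return(v$log)
    .big_to_num(v$str)
}

#' Exact size of the decorated-tree universe |S(n,k)|
#'
#' The number of k-fold decorated trees on [n]: the per-tree decoration
#' count (2n-1)(2n)...(2n+2k-2)/k! times the tree count (2n-3)!!.
#'
#' @param n Leaf count, n >= 1.
#' @param k Number of arc pairs, k >= 0.
#' @param log Return the natural logarithm instead.
#' @return Exact count.
#' @examples
#' S_total_exact(4, 2)  # 37800
#' @export
S_total_exact <- function(n, k, log = FALSE) {
    n <- .check_count(n, "n")
    k <- .check_count(k, "k", min = 0L)
    v <- cpp_S_total(n, k)
    if (log) return(v$log)
    .big_to_num(v$str)
}

.new_asym <- function(log_value) {
    structure(list(log_value = log_value,
                   value = if (log_value < 709) exp(log_value) else Inf),
              class = "arcnets_asym")
}

#' Asymptotic approximations for the decorated-tree and network counts
#'
#' All three are evaluated in log-space, since (2/e)^n n^(n+2k-1) overflows
#' doubles near n = 120.
#' \describe{
#'   \item{`S_asym(n,k)`}{|S(n,k)| ~ (2^(2k-1) sqrt(2) / k!) (2/e)^n n^(n+2k-1);}
#'   \item{`N_asym(n,k)`}{N(n,k) ~ (2^(k-1) sqrt(2) / k!) (2/e)^n n^(n+2k-1),
#'     the same expression divided by 2^k (each normal network displays 2^k
#'     trees); also the asymptotics of H(n,k);}
#'   \item{`NH_diff_asym(n)`}{N(n,2) - H(n,2) ~ (2 sqrt(2)/3) (2/e)^n n^(n+2).}
#' }
#'
#' @param n Leaf count.
#' @param k Number of reticulations.
#' @return An object of class `arcnets_asym` with fields `log_value` and
#'   `value` (`Inf` when the rendering overflows).
#' @examples
#' S_asym(50, 2)$log_value - N_asym(50, 2)$log_value  # = 2 * log(2)
#' @export
S_asym <- function(n, k) {
    n <- .check_count(n, "n")
    k <- .check_count(k, "k", min = 0L)
    .new_asym((2 * k - 1) * log(2) + 0.5 * log(2) - lfactorial(k) +
              n * (log(2) - 1) + (n + 2 * k - 1) * log(n))
}

#' @rdname S_asym
#' @export
N_asym <- function(n, k) {
    n <- .check_count(n, "n")
    k <- .check_count(k, "k", min = 0L)
    .new_asym((k - 1) * log(2) + 0.5 * log(2) - lfactorial(k) +
              n * (log(2) - 1) + (n + 2 * k - 1) * log(n))
}

#' @rdname S_asym
#' @export
NH_diff_asym <- function(n) {
    n <- .check_count(n, "n")
    .new_asym(log(2 * sqrt(2) / 3) + n * (log(2) - 1) + (n + 2) * log(n))
}

#' @export
print.arcnets_asym <- function(x, ...) {
    cat(sprintf("asymptotic value: exp(%.6f)", x$log_value))
    if (is.finite(x$value)) cat(sprintf(" = %.6g", x$value))
    cat("\n")
    invisible(x)
}
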