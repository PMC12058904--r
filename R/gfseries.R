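# Truncated power series with exact rational coefficients, backing the
# exponential generating functions r(z), H_1(z), H_2(z). All arithmetic is
# exact; no floating point enters this module.

new_rat_series <- function(lst) {
    structure(list(num = as.character(lst$num), den = as.character(lst$den),
                   order = as.integer(lst$order)),
              class = "rat_series")
}

#' Construct a truncated rational power series
#'
#' @param num Coefficient numerators: a numeric vector of integers or a
#'   character vector of decimal integer strings, giving c_0..c_N.
#' @param den Matching denominators (default all 1).
#' @return A `rat_series` of order N = `length(num) - 1`.
#' @examples
#' one_minus_2z <- rat_series(c(1, -2, 0, 0, 0))
#' @export
rat_series <- function(num, den = rep("1", length(num))) {
    if (is.numeric(num)) {
        stopifnot(all(num == round(num)))
        num <- sprintf("%.0f", num)
    }
    if (is.numeric(den)) {
        stopifnot(all(den == round(den)))
        den <- sprintf("%.0f", den)
    }
    stopifnot(length(num) == length(den), length(num) >= 1L)
    # run through one exact operation to normalize (reduce) the fractions
    z <- rep("0", length(num))
    o <- rep("1", length(num))
    new_rat_series(cpp_series_op("add", num, den, z, o, 0L))
}

#' Exponential generating function of phylogenetic trees
#'
#' The series r(z) = sum_n r_n z^n / n! = 1 - sqrt(1 - 2z), whose n-th EGF
#' coefficient n! \[z^n\] equals the tree count (2n-3)!!. The square root is
#' computed term by term over exact rationals.
#'
#' @param N Truncation order (N >= 1; kept at or below 64 in practice --
#'   coefficients grow super-exponentially but stay cheap as big rationals).
#' @return A `rat_series`.
#' @examples
#' egf_coeff(series_r(8), 8)  # 135135 = 13!!
#' @export
series_r <- function(N) {
    N <- .check_count(N, "N")
    new_rat_series(cpp_series_r(N))
}

#' Generating function of one-reticulation hybridization networks
#'
#' H_1(z) = (1/2) r(z)^3 / (1 - r(z))^3; its EGF coefficients are the counts
#' H(n,1) = N(n,1) of [H1_exact()].
#'
#' @param N Truncation order (N >= 3).
#' @return A `rat_series`.
#' @export
H1_series <- function(N) {
    N <- .check_count(N, "N", min = 3L)
    new_rat_series(cpp_series_H1(N))
}

#' Generating function of two-reticulation hybridization networks
#'
#' Three equivalent constructions of H_2(z), all with exact rational
#' coefficients:
#' \describe{
#'   \item{`"cases"`}{assembles the three root bridgeless-component cases
#'     (0, 1, or 2 reticulations in the root component) and solves the
#'     fixed-point equation H_2 = H_2 r + ... by dividing through by 1 - r;}
#'   \item{`"solved"`}{the explicitly solved expression in r and H_1;}
#'   \item{`"partial_fractions"`}{the expansion
#'     (15/8)(1-r)^-7 - 6(1-r)^-6 + (27/8)(1-r)^-5 + 9(1-r)^-4
#'     - (123/8)(1-r)^-3 + 9(1-r)^-2 - (15/8)(1-r)^-1.}
#' }
#' The three agree coefficient-by-coefficient, which guards against a
#' transcription slip in any one form.
#'
#' @param N Truncation order (N >= 4).
#' @param form Which construction to evaluate.
#' @return A `rat_series` whose EGF coefficients are H(n,2).
#' @examples
#' egf_coeff(H2_series(6), 6)  # 66960
#' @export
H2_series <- function(N, form = c("solved", "cases", "partial_fractions")) {
    N <- .check_count(N, "N", min = 4L)
    form <- match.arg(form)
    new_rat_series(cpp_series_H2(N, form))
}

#' Exact EGF coefficient extraction
#'
#' Returns n! \[z^n\] s as an exact rational: an integer (numeric, or a
#' decimal string beyond 2^53) when the denominator is 1, otherwise a
#' `"p/q"` string.
#'
#' @param s A `rat_series`.
#' @param n Coefficient index, 0 <= n <= order(s).
#' @return Exact value as described.
#' @export
egf_coeff <- function(s, n) {
    stopifnot(inherits(s, "rat_series"))
    n <- .check_count(n, "n", min = 0L)
    if (n > s$order) stop("coefficient index ", n, " exceeds truncation order ", s$order)
    v <- cpp_egf_coeff(s$num, s$den, n)
    if (v$den == "1") return(.big_to_num(v$num))
    paste0(v$num, "/", v$den)
}

.series_binop <- function(op, a, b) {
    stopifnot(inherits(a, "rat_series"), inherits(b, "rat_series"))
    if (a$order != b$order) stop("series orders differ (", a$order, " vs ", b$order, ")")
    new_rat_series(cpp_series_op(op, a$num, a$den, b$num, b$den, 0L))
}

#' Arithmetic on truncated rational series
#'
#' Exact sum, difference, product, quotient (requires an invertible constant
#' term), nonnegative integer powers, and square root (requires constant
#' term 1), all truncated at the common order.
#'
#' @param a,b `rat_series` objects of equal order.
#' @param e Nonnegative integer exponent.
#' @return A `rat_series`.
#' @examples
#' s <- series_sqrt(rat_series(c(1, -2, 0, 0)))
#' series_mul(s, s)  # back to 1 - 2z
#' @export
series_add <- function(a, b) .series_binop("add", a, b)

#' @rdname series_add
#' @export
series_sub <- function(a, b) .series_binop("sub", a, b)

#' @rdname series_add
#' @export
series_mul <- function(a, b) .series_binop("mul", a, b)

#' @rdname series_add
#' @export
series_div <- function(a, b) .series_binop("div", a, b)

#' @rdname series_add
#' @export
series_pow <- function(a, e) {
    stopifnot(inherits(a, "rat_series"))
    e <- .check_count(e, "e", min = 0L)
    new_rat_series(cpp_series_op("pow", a$num, a$den, "0", "1", e))
}

#' @rdname series_add
#' @export
series_sqrt <- function(a) {
    stopifnot(inherits(a, "rat_series"))
    new_rat_series(cpp_series_op("sqrt", a$num, a$den, "0", "1", 0L))
}

#' @export
print.rat_series <- function(x, ...) {
    cat("Truncated rational power series, order", x$order, "\n")
    show <- min(x$order, 8L)
    co <- vapply(0:show, function(i)
        if (x$den[i + 1L] == "1") x$num[i + 1L]
        else paste0(x$num[i + 1L], "/", x$den[i + 1L]), character(1))
    cat("coefficients c_0..c_", show, ": ", paste(co, collapse = ", "),
        if (x$order > show) ", ..." else "", "\n", sep = "")
    invisible(x)
}

#' @export
`==.rat_series` <- function(e1, e2) {
    identical(e1$num, e2$num) && identical(e1$den, e2$den)
}
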