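// Exact counting formulas and the truncated exponential-generating-function
// engine, both over exact big-integer / big-rational arithmetic.
#include <Rcpp.h>
#include "bigint.h"

using namespace Rcpp;
using arcnets::BigInt;
using arcnets::Rational;
using arcnets::big_factorial;
using arcnets::big_pow2;
using arcnets::big_semifactorial;

// ---------------------------------------------------------------- formulas

static List big_out(const BigInt &v) {
    return List::create(_["str"] = v.str(), _["log"] = v.log_abs(),
                        _["sign"] = v.sign);
}

// number of rooted binary phylogenetic trees on [n]: (2n-3)!!, computed via
// the factorial identity (2n-2)! / (2^(n-1) (n-1)!)
// [[Rcpp::export]]
List cpp_count_trees(int n) {
    if (n < 1) stop("n must be >= 1");
    BigInt num = big_factorial(2LL * n - 2);
    BigInt den = big_pow2(n - 1) * big_factorial(n - 1);
    return big_out(num.div_exact(den));
}

// |S(T,k)| = (2n-1)(2n)...(2n+2k-2) / k!
// [[Rcpp::export]]
List cpp_count_decorations(int n, int k) {
    if (n < 1) stop("n must be >= 1");
    if (k < 0) stop("k must be >= 0");
    BigInt p(1);
    for (int j = 0; j <= 2 * k - 1; ++j) p = p * BigInt(2LL * n - 1 + j);
    return big_out(p.div_exact(big_factorial(k)));
}

static BigInt H1_big(long long n) {
    // ((2n+1)!! + 3 (2n-1)!!)/2 - 3 n! 2^(n-1)
    BigInt a = big_semifactorial(2 * n + 1) + BigInt(3) * big_semifactorial(2 * n - 1);
    return a.div_exact(BigInt(2)) - BigInt(3) * big_factorial(n) * big_pow2(n - 1);
}

static BigInt H2_big(long long n) {
    // (2n-1)!! (n^3 + 9n^2 - 16n - 12) - 3 n! 2^n (n^2 - 4)
    BigInt poly(n * n * n + 9 * n * n - 16 * n - 12);
    return big_semifactorial(2 * n - 1) * poly -
           BigInt(3) * big_factorial(n) * big_pow2(n) * BigInt(n * n - 4);
}

static BigInt N2_big(long long n) {
    // (1/3) (2n-1)!! (3n-4) (n^2+11n+6) - n! 2^n (3n^2+2n-8)
    BigInt a = big_semifactorial(2 * n - 1) * BigInt(3 * n - 4) * BigInt(n * n + 11 * n + 6);
    return a.div_exact(BigInt(3)) -
           big_factorial(n) * big_pow2(n) * BigInt(3 * n * n + 2 * n - 8);
}

// [[Rcpp::export]]
List cpp_H1_exact(int n) {
    if (n < 3) stop("H1 closed form requires n >= 3");
    return big_out(H1_big(n));
}

// [[Rcpp::export]]
List cpp_H2_exact(int n) {
    if (n < 4) stop("H2 closed form requires n >= 4");
    return big_out(H2_big(n));
}

// [[Rcpp::export]]
List cpp_N2_exact(int n) {
    if (n < 4) stop("N2 closed form requires n >= 4");
    return big_out(N2_big(n));
}

// [[Rcpp::export]]
List cpp_N2_minus_H2(int n) {
    if (n < 4) stop("requires n >= 4");
    return big_out(N2_big(n) - H2_big(n));
}

// |S(n,k)| = count_decorations(n,k) * r_n
// [[Rcpp::export]]
List cpp_S_total(int n, int k) {
    if (n < 1 || k < 0) stop("need n >= 1, k >= 0");
    BigInt p(1);
    for (int j = 0; j <= 2 * k - 1; ++j) p = p * BigInt(2LL * n - 1 + j);
    BigInt dec = p.div_exact(big_factorial(k));
    BigInt rn = big_factorial(2LL * n - 2).div_exact(big_pow2(n - 1) * big_factorial(n - 1));
    return big_out(dec * rn);
}

// ---------------------------------------------------------------- series

typedef std::vector<Rational> Series; // coefficients c_0..c_N of z^0..z^N

static Series s_const(int N, const Rational &c0) {
    Series s(N + 1, Rational(0));
    s[0] = c0;
    return s;
}

static Series s_add(const Series &a, const Series &b) {
    Series r(a.size());
    for (size_t i = 0; i < a.size(); ++i) r[i] = a[i] + b[i];
    return r;
}

static Series s_sub(const Series &a, const Series &b) {
    Series r(a.size());
    for (size_t i = 0; i < a.size(); ++i) r[i] = a[i] - b[i];
    return r;
}

static Series s_mul(const Series &a, const Series &b) {
    Series r(a.size(), Rational(0));
    for (size_t i = 0; i < a.size(); ++i) {
        if (a[i].is_zero()) continue;
        for (size_t j = 0; i + j < a.size(); ++j) {
            if (b[j].is_zero()) continue;
            r[i + j] = r[i + j] + a[i] * b[j];
        }
    }
    return r;
}

static Series s_scale(const Series &a, const Rational &c) {
    Series r(a.size());
    for (size_t i = 0; i < a.size(); ++i) r[i] = a[i] * c;
    return r;
}

// quotient c = a / b, requires b[0] != 0:
// c_n = (a_n - sum_{i=1..n} b_i c_{n-i}) / b_0
static Series s_div(const Series &a, const Series &b) {
    if (b[0].is_zero())
        throw std::runtime_error("series quotient needs invertible constant term");
    Series c(a.size(), Rational(0));
    for (size_t n = 0; n < a.size(); ++n) {
        Rational acc = a[n];
        for (size_t i = 1; i <= n; ++i)
            if (!b[i].is_zero() && !c[n - i].is_zero())
                acc = acc - b[i] * c[n - i];
        c[n] = acc / b[0];
    }
    return c;
}

static Series s_pow(const Series &a, int e) {
    if (e < 0) throw std::runtime_error("series power needs e >= 0");
    Series r = s_const(static_cast<int>(a.size()) - 1, Rational(1));
    for (int i = 0; i < e; ++i) r = s_mul(r, a);
    return r;
}

// square root with a[0] == 1:  s_0 = 1,
// s_n = (a_n - sum_{i=1..n-1} s_i s_{n-i}) / 2
static Series s_sqrt(const Series &a) {
    if (!(a[0] == Rational(1)))
        throw std::runtime_error("series sqrt needs constant term 1");
    Series s(a.size(), Rational(0));
    s[0] = Rational(1);
    for (size_t n = 1; n < a.size(); ++n) {
        Rational acc = a[n];
        for (size_t i = 1; i < n; ++i) acc = acc - s[i] * s[n - i];
        s[n] = acc / Rational(2);
    }
    return s;
}

static Series series_r_int(int N) {
    // r(z) = 1 - sqrt(1 - 2z)
    Series a = s_const(N, Rational(1));
    if (N >= 1) a[1] = Rational(-2);
    Series s = s_sqrt(a);
    return s_sub(s_const(N, Rational(1)), s);
}

static Series series_H1_int(int N) {
    // H_1(z) = (1/2) r^3 / (1-r)^3
    Series r = series_r_int(N);
    Series omr = s_sub(s_const(N, Rational(1)), r);
    Series h = s_div(s_pow(r, 3), s_pow(omr, 3));
    return s_scale(h, Rational(1, 2));
}

static Series series_H2_int(int N, const std::string &form) {
    Series r = series_r_int(N);
    Series omr = s_sub(s_const(N, Rational(1)), r); // 1 - r
    Series h1 = series_H1_int(N);
    if (form == "cases") {
        // fixed point H2 = H2 r + A  =>  H2 = A / (1 - r), with A the
        // root-component case terms (bridgeless-component decomposition)
        Series A = s_scale(s_mul(h1, h1), Rational(1, 2));
        A = s_add(A, s_mul(h1, s_div(s_pow(r, 2), s_pow(omr, 3))));
        A = s_add(A, s_scale(s_mul(h1, s_div(s_pow(r, 2), s_pow(omr, 2))), Rational(1, 2)));
        A = s_add(A, s_scale(s_div(s_pow(r, 4), s_pow(omr, 4)), Rational(1, 2)));
        A = s_add(A, s_div(s_pow(r, 4), s_pow(omr, 5)));
        A = s_add(A, s_scale(s_div(s_pow(r, 5), s_pow(omr, 5)), Rational(7, 2)));
        A = s_add(A, s_scale(s_div(s_pow(r, 6), s_pow(omr, 6)), Rational(5, 4)));
        return s_div(A, omr);
    } else if (form == "solved") {
        Series h = s_scale(s_div(s_mul(h1, h1), omr), Rational(1, 2));
        h = s_add(h, s_mul(h1, s_div(s_pow(r, 2), s_pow(omr, 4))));
        h = s_add(h, s_scale(s_mul(h1, s_div(s_pow(r, 2), s_pow(omr, 3))), Rational(1, 2)));
        h = s_add(h, s_scale(s_div(s_pow(r, 4), s_pow(omr, 5)), Rational(1, 2)));
        h = s_add(h, s_div(s_pow(r, 4), s_pow(omr, 6)));
        h = s_add(h, s_scale(s_div(s_pow(r, 5), s_pow(omr, 6)), Rational(7, 2)));
        h = s_add(h, s_scale(s_div(s_pow(r, 6), s_pow(omr, 7)), Rational(5, 4)));
        return h;
    } else if (form == "partial_fractions") {
        // sum_j c_j (1-r)^(-j), j = 7..1
        const long long nums[7] = {15, -48, 27, 72, -123, 72, -15};
        // coefficients 15/8, -6, 27/8, 9, -123/8, 9, -15/8 over common den 8
        Series one = s_const(N, Rational(1));
        Series h(N + 1, Rational(0));
        for (int j = 7; j >= 1; --j) {
            Series term = s_div(one, s_pow(omr, j));
            h = s_add(h, s_scale(term, Rational(nums[7 - j], 8)));
        }
        return h;
    }
    throw std::runtime_error("unknown H2 form: " + form);
}

static List series_out(const Series &s) {
    int N = static_cast<int>(s.size()) - 1;
    CharacterVector num(N + 1), den(N + 1);
    for (int i = 0; i <= N; ++i) {
        num[i] = s[i].num.str();
        den[i] = s[i].den.str();
    }
    return List::create(_["num"] = num, _["den"] = den, _["order"] = N);
}

static Series series_in(const CharacterVector &num, const CharacterVector &den) {
    if (num.size() != den.size()) throw std::runtime_error("coefficient length mismatch");
    Series s(num.size());
    for (int i = 0; i < num.size(); ++i)
        s[i] = Rational(BigInt::parse(as<std::string>(num[i])),
                        BigInt::parse(as<std::string>(den[i])));
    return s;
}

// [[Rcpp::export]]
List cpp_series_r(int N) {
    if (N < 1) stop("order must be >= 1");
    return series_out(series_r_int(N));
}

// [[Rcpp::export]]
List cpp_series_H1(int N) {
    if (N < 3) stop("order must be >= 3");
    return series_out(series_H1_int(N));
}

// [[Rcpp::export]]
List cpp_series_H2(int N, std::string form) {
    if (N < 4) stop("order must be >= 4");
    return series_out(series_H2_int(N, form));
}

// [[Rcpp::export]]
List cpp_series_op(std::string op, CharacterVector anum, CharacterVector aden,
                   CharacterVector bnum, CharacterVector bden, int e) {
    Series a = series_in(anum, aden);
    if (op == "sqrt") return series_out(s_sqrt(a));
    if (op == "pow") return series_out(s_pow(a, e));
    Series b = series_in(bnum, bden);
    if (op == "add") return series_out(s_add(a, b));
    if (op == "sub") return series_out(s_sub(a, b));
    if (op == "mul") return series_out(s_mul(a, b));
    if (op == "div") return series_out(s_div(a, b));
    stop("unknown series op: %s", op.c_str());
}

// n! [z^n] s, as an exact rational
// [[Rcpp::export]]
List cpp_egf_coeff(CharacterVector num, CharacterVector den, int n) {
    if (n < 0 || n >= num.size()) stop("coefficient index outside truncation order");
    Rational c(BigInt::parse(as<std::string>(num[n])),
               BigInt::parse(as<std::string>(den[n])));
    Rational v = c * Rational(big_factorial(n));
    return List::create(_["num"] = v.num.str(), _["den"] = v.den.str(),
                        _["log"] = v.num.log_abs() - v.den.log_abs(),
                        _["sign"] = v.num.sign);
}
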