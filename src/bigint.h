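// Arbitrary-precision signed integers and rationals.
// Sign + magnitude, little-endian base 2^32 limbs. Division is bit-serial
// long division; gcd is binary (shift/subtract). Magnitudes in this package
// stay below a few thousand bits, where these O(bits * limbs) algorithms are
// more than fast enough and easy to audit.
#pragma once

#include <vector>
#include <string>
#include <cstdint>
#include <stdexcept>
#include <algorithm>
#include <limits>
#include <cmath>

namespace arcnets {

typedef std::vector<uint32_t> Mag; // little-endian magnitude, no trailing zeros

inline void mag_trim(Mag &a) { while (!a.empty() && a.back() == 0) a.pop_back(); }

inline int mag_cmp(const Mag &a, const Mag &b) {
    if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
    for (size_t i = a.size(); i-- > 0;)
        if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
    return 0;
}

inline Mag mag_add(const Mag &a, const Mag &b) {
    Mag r;
    size_t m = std::max(a.size(), b.size());
    r.reserve(m + 1);
    uint64_t carry = 0;
    for (size_t i = 0; i < m || carry; ++i) {
        uint64_t s = carry;
        if (i < a.size()) s += a[i];
        if (i < b.size()) s += b[i];
        r.push_back(static_cast<uint32_t>(s));
        carry = s >> 32;
    }
    mag_trim(r);
    return r;
}

// requires a >= b
inline Mag mag_sub(const Mag &a, const Mag &b) {
    Mag r = a;
    int64_t borrow = 0;
    for (size_t i = 0; i < a.size(); ++i) {
        int64_t s = static_cast<int64_t>(a[i]) - borrow - (i < b.size() ? b[i] : 0);
        if (s < 0) { s += (static_cast<int64_t>(1) << 32); borrow = 1; } else borrow = 0;
        r[i] = static_cast<uint32_t>(s);
    }
    mag_trim(r);
    return r;
}

inline Mag mag_mul(const Mag &a, const Mag &b) {
    if (a.empty() || b.empty()) return Mag();
    Mag r(a.size() + b.size(), 0);
    for (size_t i = 0; i < a.size(); ++i) {
        uint64_t carry = 0, ai = a[i];
        size_t j = 0;
        for (; j < b.size(); ++j) {
            uint64_t cur = r[i + j] + ai * b[j] + carry;
            r[i + j] = static_cast<uint32_t>(cur);
            carry = cur >> 32;
        }
        while (carry) {
            uint64_t cur = r[i + j] + carry;
            r[i + j] = static_cast<uint32_t>(cur);
            carry = cur >> 32;
            ++j;
        }
    }
    mag_trim(r);
    return r;
}

inline int mag_bitlen(const Mag &a) {
    if (a.empty()) return 0;
    uint32_t top = a.back();
    int b = 0;
    while (top) { ++b; top >>= 1; }
    return static_cast<int>((a.size() - 1) * 32) + b;
}

inline bool mag_getbit(const Mag &a, int i) {
    size_t w = static_cast<size_t>(i) / 32;
    if (w >= a.size()) return false;
    return (a[w] >> (i % 32)) & 1u;
}

// in-place left shift by one bit
inline void mag_shl1(Mag &a) {
    uint32_t carry = 0;
    for (size_t i = 0; i < a.size(); ++i) {
        uint32_t nc = a[i] >> 31;
        a[i] = (a[i] << 1) | carry;
        carry = nc;
    }
    if (carry) a.push_back(carry);
}

inline void mag_shl(Mag &a, int s) {
    if (a.empty() || s == 0) return;
    int words = s / 32, bits = s % 32;
    Mag r(a.size() + words + 1, 0);
    for (size_t i = 0; i < a.size(); ++i) {
        uint64_t v = static_cast<uint64_t>(a[i]) << bits;
        r[i + words] |= static_cast<uint32_t>(v);
        r[i + words + 1] |= static_cast<uint32_t>(v >> 32);
    }
    mag_trim(r);
    a.swap(r);
}

inline void mag_shr(Mag &a, int s) {
    if (a.empty() || s == 0) return;
    int words = s / 32, bits = s % 32;
    if (static_cast<size_t>(words) >= a.size()) { a.clear(); return; }
    for (size_t i = 0; i + words < a.size(); ++i) {
        uint64_t v = a[i + words];
        if (bits) {
            v >>= bits;
            if (i + words + 1 < a.size())
                v |= (static_cast<uint64_t>(a[i + words + 1]) << (32 - bits));
        }
        a[i] = static_cast<uint32_t>(v);
    }
    a.resize(a.size() - words);
    mag_trim(a);
}

inline int mag_ctz(const Mag &a) { // trailing zero bits; a non-empty
    int c = 0;
    for (size_t i = 0; i < a.size(); ++i) {
        if (a[i] == 0) { c += 32; continue; }
        uint32_t v = a[i];
        while (!(v & 1)) { ++c; v >>= 1; }
        break;
    }
    return c;
}

// bit-serial long division: a = q*b + r, 0 <= r < b
inline void mag_divmod(const Mag &a, const Mag &b, Mag &q, Mag &r) {
    if (b.empty()) throw std::runtime_error("bigint: division by zero");
    q.assign(a.size(), 0);
    r.clear();
    for (int i = mag_bitlen(a) - 1; i >= 0; --i) {
        mag_shl1(r);
        if (mag_getbit(a, i)) {
            if (r.empty()) r.push_back(0);
            r[0] |= 1u;
        }
        if (mag_cmp(r, b) >= 0) {
            r = mag_sub(r, b);
            q[static_cast<size_t>(i) / 32] |= (1u << (i % 32));
        }
    }
    mag_trim(q);
    mag_trim(r);
}

inline Mag mag_gcd(Mag a, Mag b) {
    if (a.empty()) return b;
    if (b.empty()) return a;
    int sa = mag_ctz(a), sb = mag_ctz(b);
    int shift = std::min(sa, sb);
    mag_shr(a, sa);
    for (;;) {
        mag_shr(b, mag_ctz(b));
        if (mag_cmp(a, b) > 0) std::swap(a, b);
        b = mag_sub(b, a);
        if (b.empty()) break;
    }
    mag_shl(a, shift);
    return a;
}

// divide by a single small limb; returns remainder
inline uint32_t mag_divsmall(Mag &a, uint32_t d) {
    uint64_t rem = 0;
    for (size_t i = a.size(); i-- > 0;) {
        uint64_t cur = (rem << 32) | a[i];
        a[i] = static_cast<uint32_t>(cur / d);
        rem = cur % d;
    }
    mag_trim(a);
    return static_cast<uint32_t>(rem);
}

inline void mag_mulsmall_add(Mag &a, uint32_t m, uint32_t add) {
    uint64_t carry = add;
    for (size_t i = 0; i < a.size(); ++i) {
        uint64_t cur = static_cast<uint64_t>(a[i]) * m + carry;
        a[i] = static_cast<uint32_t>(cur);
        carry = cur >> 32;
    }
    while (carry) {
        a.push_back(static_cast<uint32_t>(carry));
        carry >>= 32;
    }
    mag_trim(a);
}

struct BigInt {
    int sign;  // -1, 0, +1
    Mag mag;

    BigInt() : sign(0) {}
    BigInt(long long v) : sign(0) {
        unsigned long long u;
        if (v < 0) { sign = -1; u = static_cast<unsigned long long>(-v); }
        else if (v > 0) { sign = 1; u = static_cast<unsigned long long>(v); }
        else u = 0;
        while (u) { mag.push_back(static_cast<uint32_t>(u)); u >>= 32; }
    }

    bool is_zero() const { return sign == 0; }

    static BigInt from_mag(const Mag &m, int s) {
        BigInt r;
        r.mag = m;
        r.sign = m.empty() ? 0 : s;
        return r;
    }

    BigInt operator-() const { return from_mag(mag, -sign); }

    BigInt operator+(const BigInt &o) const {
        if (sign == 0) return o;
        if (o.sign == 0) return *this;
        if (sign == o.sign) return from_mag(mag_add(mag, o.mag), sign);
        int c = mag_cmp(mag, o.mag);
        if (c == 0) return BigInt();
        if (c > 0) return from_mag(mag_sub(mag, o.mag), sign);
        return from_mag(mag_sub(o.mag, mag), o.sign);
    }
    BigInt operator-(const BigInt &o) const { return *this + (-o); }
    BigInt operator*(const BigInt &o) const {
        return from_mag(mag_mul(mag, o.mag), sign * o.sign);
    }

    // truncated division (sign of quotient = product of signs); only used
    // where divisions are exact or operands nonnegative
    void divmod(const BigInt &o, BigInt &q, BigInt &r) const {
        Mag qm, rm;
        mag_divmod(mag, o.mag, qm, rm);
        q = from_mag(qm, sign * o.sign);
        r = from_mag(rm, sign);
    }

    BigInt div_exact(const BigInt &o) const {
        BigInt q, r;
        divmod(o, q, r);
        if (!r.is_zero()) throw std::runtime_error("bigint: inexact division");
        return q;
    }

    int cmp(const BigInt &o) const {
        if (sign != o.sign) return sign < o.sign ? -1 : 1;
        int c = mag_cmp(mag, o.mag);
        return sign >= 0 ? c : -c;
    }
    bool operator==(const BigInt &o) const { return cmp(o) == 0; }
    bool operator<(const BigInt &o) const { return cmp(o) < 0; }

    std::string str() const {
        if (sign == 0) return "0";
        Mag a = mag;
        std::string out;
        while (!a.empty()) {
            uint32_t rem = mag_divsmall(a, 1000000000u);
            if (a.empty()) {
                out = std::to_string(rem) + out;
            } else {
                std::string chunk = std::to_string(rem);
                out = std::string(9 - chunk.size(), '0') + chunk + out;
            }
        }
        return (sign < 0 ? "-" : "") + out;
    }

    static BigInt parse(const std::string &s) {
        BigInt r;
        size_t i = 0;
        int sgn = 1;
        if (i < s.size() && (s[i] == '-' || s[i] == '+')) {
            if (s[i] == '-') sgn = -1;
            ++i;
        }
        if (i >= s.size()) throw std::runtime_error("bigint: empty string");
        for (; i < s.size(); ++i) {
            if (s[i] < '0' || s[i] > '9')
                throw std::runtime_error("bigint: bad digit in '" + s + "'");
            mag_mulsmall_add(r.mag, 10u, static_cast<uint32_t>(s[i] - '0'));
        }
        r.sign = r.mag.empty() ? 0 : sgn;
        return r;
    }

    // natural log of |x|; -inf for zero
    double log_abs() const {
        if (sign == 0) return -std::numeric_limits<double>::infinity();
        int L = mag_bitlen(mag);
        int take = std::min(L, 64);
        uint64_t m = 0;
        for (int i = 0; i < take; ++i)
            if (mag_getbit(mag, L - 1 - i)) m |= (1ull << (take - 1 - i));
        return std::log(static_cast<double>(m)) + (L - take) * M_LN2;
    }

    double to_double() const {
        if (sign == 0) return 0.0;
        int L = mag_bitlen(mag);
        int take = std::min(L, 64);
        uint64_t m = 0;
        for (int i = 0; i < take; ++i)
            if (mag_getbit(mag, L - 1 - i)) m |= (1ull << (take - 1 - i));
        double v = std::ldexp(static_cast<double>(m), L - take);
        return sign < 0 ? -v : v;
    }
};

inline BigInt big_factorial(long long n) {
    BigInt r(1);
    for (long long i = 2; i <= n; ++i) r = r * BigInt(i);
    return r;
}

inline BigInt big_pow2(long long e) {
    BigInt r(1);
    Mag m;
    m.resize(static_cast<size_t>(e / 32) + 1, 0);
    m[static_cast<size_t>(e / 32)] = (1u << (e % 32));
    r.mag = m;
    r.sign = 1;
    return r;
}

// product of odd numbers 1*3*...*m (m odd); m <= 1 -> 1
inline BigInt big_semifactorial(long long m) {
    BigInt r(1);
    for (long long i = 3; i <= m; i += 2) r = r * BigInt(i);
    return r;
}

struct Rational {
    BigInt num, den;  // den > 0, gcd(num,den) = 1

    Rational() : num(0), den(1) {}
    Rational(const BigInt &n) : num(n), den(1) {}
    Rational(long long n) : num(n), den(1) {}
    Rational(const BigInt &n, const BigInt &d) : num(n), den(d) { normalize(); }
    Rational(long long n, long long d) : num(n), den(d) { normalize(); }

    void normalize() {
        if (den.is_zero()) throw std::runtime_error("rational: zero denominator");
        if (den.sign < 0) { den = -den; num = -num; }
        if (num.is_zero()) { den = BigInt(1); return; }
        Mag g = mag_gcd(num.mag, den.mag);
        if (!(g.size() == 1 && g[0] == 1)) {
            BigInt gb = BigInt::from_mag(g, 1);
            num = num.div_exact(gb);
            den = den.div_exact(gb);
        }
    }

    bool is_zero() const { return num.is_zero(); }
    bool is_integer() const { return den.mag.size() == 1 && den.mag[0] == 1; }

    Rational operator+(const Rational &o) const {
        return Rational(num * o.den + o.num * den, den * o.den);
    }
    Rational operator-(const Rational &o) const {
        return Rational(num * o.den - o.num * den, den * o.den);
    }
    Rational operator*(const Rational &o) const {
        return Rational(num * o.num, den * o.den);
    }
    Rational operator/(const Rational &o) const {
        if (o.is_zero()) throw std::runtime_error("rational: division by zero");
        return Rational(num * o.den, den * o.num);
    }
    bool operator==(const Rational &o) const {
        return num == o.num && den == o.den;
    }
};

} // namespace arcnets
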