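# Exact rational series engine for the exponential generating functions.

test_that("the tree EGF r(z) = 1 - sqrt(1-2z) reproduces the semifactorials", {
    r <- series_r(8)
    expect_equal(egf_coeff(r, 1), 1)
    expect_equal(egf_coeff(r, 4), 15)
    expect_equal(egf_coeff(r, 8), 135135) # 13!!
    expect_equal(egf_coeff(r, 0), 0)
    for (n in 1:8) expect_equal(egf_coeff(r, n), count_trees(n))
})

test_that("the series square root squares back exactly", {
    N <- 16
    one_minus_2z <- rat_series(c(1, -2, rep(0, N - 1)))
    s <- series_sqrt(one_minus_2z)
    expect_true(series_mul(s, s) == one_minus_2z)
    # and r = 1 - s matches the builtin construction
    one <- rat_series(c(1, rep(0, N)))
    expect_true(series_sub(one, s) == series_r(N))
})

test_that("series arithmetic identities hold exactly", {
    N <- 10
    r <- series_r(N)
    one <- rat_series(c(1, rep(0, N)))
    omr <- series_sub(one, r)
    # division is the inverse of multiplication
    q <- series_div(r, omr)
    expect_true(series_mul(q, omr) == r)
    # powers agree with repeated products
    expect_true(series_pow(r, 3) == series_mul(r, series_mul(r, r)))
    expect_error(series_div(r, series_sub(one, one)), "invertible")
    expect_error(series_sqrt(series_add(one, one)), "constant term 1")
})

test_that("H1 series coefficients match the closed form for n = 3..12", {
    h1 <- H1_series(12)
    expect_equal(egf_coeff(h1, 0), 0)
    expect_equal(egf_coeff(h1, 1), 0)
    expect_equal(egf_coeff(h1, 2), 0)   # smallest such network has 3 leaves
    expect_equal(egf_coeff(h1, 4), 54)
    for (n in 3:12) expect_equal(egf_coeff(h1, n), H1_exact(n))
})

test_that("the three H2 constructions agree exactly to order 12 and match the closed form", {
    cases <- H2_series(12, form = "cases")
    solved <- H2_series(12, form = "solved")
    pf <- H2_series(12, form = "partial_fractions")
    expect_true(cases == solved)
    expect_true(solved == pf)
    expect_equal(egf_coeff(cases, 4), 36)
    expect_equal(egf_coeff(cases, 5), 1890)
    expect_equal(egf_coeff(cases, 6), 66960)
    for (n in 4:12) expect_equal(egf_coeff(solved, n), H2_exact(n))
})

test_that("EGF coefficient extraction is exact and guards its domain", {
    z <- rat_series(rep(0, 7))
    expect_equal(egf_coeff(z, 5), 0)
    expect_error(egf_coeff(series_r(6), 7), "order")
    half <- rat_series("1", den = "2")
    expect_equal(egf_coeff(half, 0), "1/2")
})
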