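# The k-fold decoration process: counting, enumeration with dedup, uniform
# sampling, and the induced subdivision tree.

test_that("decoration counts follow the rising product over k!", {
    expect_equal(count_decorations(4, 0), 1)
    expect_equal(count_decorations(4, 1), 56)   # 7 * 8
    expect_equal(count_decorations(4, 2), 2520) # 7*8*9*10 / 2
    expect_equal(count_decorations(5, 2), 5940)
    expect_error(count_decorations(0, 1), "n")
    expect_error(count_decorations(4, -1), "k")
})

test_that("exhaustive decoration enumeration dedups raw sequences by exactly k!", {
    tr <- balanced4()
    d0 <- enumerate_decorations(tr, 0)
    expect_length(d0, 1)
    for (k in 1:2) {
        decs <- enumerate_decorations(tr, k)
        expect_length(decs, count_decorations(4, k))
        expect_equal(attr(decs, "raw_sequences"),
                     factorial(k) * count_decorations(4, k))
        codes <- vapply(decs, decoration_code, character(1))
        expect_length(unique(codes), length(decs))
    }
})

test_that("decoration totals over all base trees equal |S(n,k)|", {
    for (k in 0:2) {
        total <- sum(vapply(enumerate_trees(4), function(tr)
            length(enumerate_decorations(tr, k)), numeric(1)))
        expect_equal(total, S_total_exact(4, k))
    }
    expect_equal(S_total_exact(4, 1), 840)
    expect_equal(S_total_exact(4, 2), 37800)
    expect_equal(S_total_exact(5, 2), 623700)
})

test_that("random_decoration is uniform over the 56 one-pair decorations", {
    tr <- balanced4()
    codes_all <- vapply(enumerate_decorations(tr, 1), decoration_code, character(1))
    expect_length(codes_all, 56)
    set.seed(99)
    draws <- vapply(seq_len(56000), function(i)
        decoration_code(random_decoration(tr, 1)), character(1))
    tab <- table(factor(draws, levels = codes_all))
    expect_equal(sum(tab), 56000)
    p <- chisq.test(tab, p = rep(1 / 56, 56))$p.value
    expect_gt(p, 0.001)
})

test_that("random_decoration is deterministic given a seed and k = 0 is the tree", {
    tr <- caterpillar4()
    a <- random_decoration(tr, 3, seed = 7)
    b <- random_decoration(tr, 3, seed = 7)
    expect_identical(a, b)
    d0 <- random_decoration(tr, 0, seed = 1)
    expect_identical(d0$tk_edges, tr$edges)
    expect_equal(d0$k, 0L)
})

test_that("induced subdivision tree matches the two canonical k = 1 pictures", {
    side <- induced_subdivision_tree(cherry_dec_sides())
    expect_equal(side$ell, 0L)
    expect_equal(side$n_edges, 2L)  # 4k-2-ell = 2
    expect_setequal(side$vertices, c(4L, 5L, 6L))
    expect_equal(side$root, 4L)

    stacked <- induced_subdivision_tree(cherry_dec_stacked())
    expect_equal(stacked$ell, 1L)
    expect_equal(stacked$n_edges, 1L) # 4k-2-ell = 1
    expect_setequal(stacked$vertices, c(5L, 6L))
    expect_equal(stacked$root, 5L)

    expect_error(induced_subdivision_tree(random_decoration(cherry2(), 0)),
                 "k = 0")
})

test_that("subdivision-tree edge identity 4k-2-ell holds exhaustively at (4,1)", {
    for (tr in enumerate_trees(4)) {
        for (d in enumerate_decorations(tr, 1)) {
            st <- induced_subdivision_tree(d)
            expect_equal(st$n_edges, 4L * d$k - 2L - st$ell)
        }
    }
})

test_that("subdivision-tree edge identity holds on 10000 random decorations at n=20, k=5", {
    set.seed(2024)
    ok <- TRUE
    for (i in seq_len(10000)) {
        d <- random_decoration(random_tree(20), 5)
        st <- induced_subdivision_tree(d)
        if (st$n_edges != 4L * 5L - 2L - st$ell) { ok <- FALSE; break }
    }
    expect_true(ok)
})

test_that("the per-tree decoration count approaches (2n)^(2k)/k! in the moderate-k regime", {
    # log-space ratio check along n = 10^3..10^6 with k = floor(n^(1/4))
    devs <- vapply(c(1e3, 1e4, 1e5, 1e6), function(n) {
        k <- floor(n^(1 / 4))
        exact_log <- count_decorations(n, k, log = TRUE)
        approx_log <- 2 * k * log(2 * n) - lfactorial(k)
        abs(exp(exact_log - approx_log) - 1)
    }, numeric(1))
    ks <- floor(c(1e3, 1e4, 1e5, 1e6)^(1 / 4))
    expect_true(all(devs < 2 * ks^2 / c(1e3, 1e4, 1e5, 1e6)))
    expect_lt(devs[4], devs[1])
})
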