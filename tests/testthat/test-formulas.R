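# Exact closed forms and log-space asymptotics.

test_that("H1 closed form evaluates exactly on its domain", {
    expect_equal(H1_exact(3), 3)
    expect_equal(H1_exact(4), 54)
    expect_equal(H1_exact(5), 855)
    expect_equal(H1_exact(6), 14040)
    expect_error(H1_exact(2), "n")
})

test_that("H2 and N2 closed forms evaluate exactly on their domains", {
    expect_equal(H2_exact(4), 36)
    expect_equal(H2_exact(5), 1890)
    expect_equal(H2_exact(6), 66960)
    expect_equal(N2_exact(4), 48)
    expect_equal(N2_exact(5), 2310)
    expect_equal(NH2_diff_exact(4), 12)
    expect_equal(NH2_diff_exact(5), N2_exact(5) - H2_exact(5))
    expect_error(H2_exact(3), "n")
    expect_error(N2_exact(3), "n")
})

test_that("the decorated-tree universe size factors as decorations times trees", {
    expect_equal(S_total_exact(4, 0), 15)
    expect_equal(S_total_exact(4, 2), 37800)
    expect_equal(S_total_exact(5, 2), 623700)
    expect_equal(S_total_exact(5, 2), count_decorations(5, 2) * count_trees(5))
})

test_that("large exact values come back as decimal strings and exact logs", {
    v <- N2_exact(200)
    expect_type(v, "character")
    expect_true(nchar(v) > 100)
    lg <- N2_exact(200, log = TRUE)
    expect_true(is.finite(lg))
    # log value consistent with the string's magnitude
    expect_equal(lg / log(10), nchar(v) - 1, tolerance = 0.01)
})

test_that("the decorated-tree and normal-network asymptotics differ by exactly 2^k", {
    for (k in 0:4) {
        d <- S_asym(40, k)$log_value - N_asym(40, k)$log_value
        expect_equal(d, k * log(2), tolerance = 1e-12)
    }
})

test_that("exact/asymptotic ratios approach 1 along a doubling ladder of n", {
    ladder <- c(50, 100, 200, 400)
    dev_N2 <- vapply(ladder, function(n)
        abs(exp(N2_exact(n, log = TRUE) - N_asym(n, 2)$log_value) - 1), numeric(1))
    expect_true(all(diff(dev_N2) < 0))
    dev_diff <- vapply(ladder, function(n)
        abs(exp(NH2_diff_exact(n, log = TRUE) - NH_diff_asym(n)$log_value) - 1),
        numeric(1))
    expect_true(all(diff(dev_diff) < 0))
    dev_H2 <- vapply(ladder, function(n)
        abs(exp(H2_exact(n, log = TRUE) - N_asym(n, 2)$log_value) - 1), numeric(1))
    expect_true(all(diff(dev_H2) < 0))
})

test_that("H2/N2 tends to 1: within 1e-2 of 1 by n = 100", {
    ratio <- exp(H2_exact(100, log = TRUE) - N2_exact(100, log = TRUE))
    expect_lt(abs(ratio - 1), 1e-2)
    ratio50 <- exp(H2_exact(50, log = TRUE) - N2_exact(50, log = TRUE))
    expect_gt(abs(ratio50 - 1), abs(ratio - 1)) # still improving
})
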