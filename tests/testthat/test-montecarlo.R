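# Seeded Monte Carlo estimation of class proportions.

test_that("k = 0 samples are trees and hence all hybridization networks", {
    est <- estimate_proportions(6, 0, 500, seed = 5)
    expect_equal(unname(est$counts[["hybridization"]]), 500)
    expect_equal(unname(est$p_normal[["estimate"]]), 1)
    expect_equal(unname(est$p_network[["estimate"]]), 1)
})

test_that("estimates are reproducible given a seed and counts sum to M", {
    a <- estimate_proportions(10, 2, 2000, seed = 11)
    b <- estimate_proportions(10, 2, 2000, seed = 11)
    expect_identical(a$counts, b$counts)
    expect_equal(sum(a$counts), 2000)
    expect_true(all(a$per_class[, "lower"] >= 0 & a$per_class[, "upper"] <= 1))
})

test_that("Wilson intervals behave at the extremes", {
    w <- wilson_interval(0, 100)
    expect_equal(unname(w[["estimate"]]), 0)
    expect_gt(w[["upper"]], 0)
    w1 <- wilson_interval(100, 100)
    expect_lt(w1[["lower"]], 1)
    expect_equal(unname(w1[["upper"]]), 1)
})

test_that("the 95% interval covers the exact (4,1) proportion in >= 90% of 50 replicates", {
    exact <- 108 / 840 # |S_no(4,1)| / |S(4,1)| from the exhaustive census
    set.seed(314)
    hits <- vapply(seq_len(50), function(i) {
        est <- estimate_proportions(4, 1, 2000)
        est$p_normal[["lower"]] <= exact && exact <= est$p_normal[["upper"]]
    }, logical(1))
    expect_gte(mean(hits), 0.9)
})

test_that("the trend table has coherent intervals and a rising normal proportion", {
    tab <- trend_experiment(2, c(5, 20, 80), 4000, seed = 27)
    expect_equal(nrow(tab), 3L)
    expect_true(all(tab$normal_lower <= tab$p_normal & tab$p_normal <= tab$normal_upper))
    # nondecreasing up to interval overlap
    for (i in seq_len(nrow(tab) - 1)) {
        rising <- tab$p_normal[i + 1] >= tab$p_normal[i]
        overlap <- tab$normal_lower[i + 1] <= tab$normal_upper[i]
        expect_true(rising || overlap)
    }
    # at these n the trend is steep enough to be strict
    expect_gt(tab$p_normal[3], tab$p_normal[1])
})
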