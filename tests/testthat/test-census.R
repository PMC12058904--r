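# Exhaustive census pipeline: exact class counts, deduplicated network
# counts, and agreement with the closed forms.

test_that("the (4,1) census reproduces the exact counts", {
    cs <- run_census(4, 1)
    expect_equal(cs$total, 840)
    expect_equal(cs$distinct_normal, 54)
    expect_equal(cs$distinct_hyb, 54)   # k = 1: every normal network is temporal
    expect_equal(cs$S_no, 108)          # 2^1 * 54
    expect_equal(cs$S_c + cs$S_not_no + cs$S_no, cs$total)
    expect_equal(sum(cs$by_ell), cs$total)
    expect_equal(cs$distinct_normal, H1_exact(4))
})

test_that("the (4,2) census reproduces the exact counts and Eq-6 double counting", {
    cs <- run_census(4, 2, shapes = TRUE)
    expect_equal(cs$total, 37800)
    expect_equal(cs$distinct_normal, 48)
    expect_equal(cs$distinct_hyb, 36)
    expect_equal(cs$S_no, 192)          # 2^2 * 48
    expect_equal(cs$S_hyb, 144)         # 2^2 * 36
    expect_equal(cs$distinct_normal, N2_exact(4))
    expect_equal(cs$distinct_hyb, H2_exact(4))
    # three unlabeled shapes with orbits {12, 24, 12}
    expect_length(cs$shape_sizes, 3L)
    expect_equal(sort(cs$shape_sizes), c(12, 12, 24))
    expect_equal(sum(cs$shape_sizes), 48)
})

test_that("one-reticulation censuses match the closed form for n = 3..6", {
    for (n in 3:6) {
        cs <- run_census(n, 1)
        expect_equal(cs$distinct_normal, H1_exact(n))
        expect_equal(cs$distinct_hyb, H1_exact(n))
        expect_equal(cs$total, S_total_exact(n, 1))
    }
})

test_that("two-reticulation censuses match the closed forms at n = 4, 5", {
    cs5 <- run_census(5, 2)
    expect_equal(cs5$total, 623700)
    expect_equal(cs5$distinct_normal, N2_exact(5)) # 2310
    expect_equal(cs5$distinct_hyb, H2_exact(5))    # 1890
    expect_equal(cs5$S_no, 4 * 2310)
})

test_that("shape orbits sum to the labeled count at (4,1)", {
    sizes <- shape_census(4, 1)
    expect_equal(sum(sizes), 54)
    expect_true(all(sizes >= 1))
})

test_that("cyclic decorated trees always have ell >= 1 (exhaustive (4,1))", {
    # independent R-level check of the census-internal invariant
    for (tr in enumerate_trees(4)) {
        for (d in enumerate_decorations(tr, 1)) {
            if (!is_acyclic(as_network(d)))
                expect_gte(induced_subdivision_tree(d)$ell, 1L)
        }
    }
})

test_that("k = 0 censuses count the trees themselves, all hybridization", {
    cs <- run_census(4, 0)
    expect_equal(cs$total, 15)
    expect_equal(cs$distinct_normal, 15)
    expect_equal(cs$distinct_hyb, 15)
    expect_equal(unname(cs$counts["hybridization"]), 15)
})

test_that("oversize censuses are refused with a size estimate", {
    expect_error(run_census(6, 2), "refused")
    expect_error(run_census(6, 2), "11351340") # |S(6,2)| quoted in the refusal
    expect_error(run_census(9, 0), "refused")
})
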