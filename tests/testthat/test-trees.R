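# Base trees: counting, exhaustive enumeration, uniform sampling, Newick I/O.

test_that("tree counts follow the semifactorial and match enumeration", {
    expect_equal(count_trees(1), 1)
    expect_equal(count_trees(2), 1)
    expect_equal(count_trees(4), 15)
    expect_equal(count_trees(6), 945)
    expect_error(count_trees(0), "n")
    for (n in 1:6)
        expect_length(enumerate_trees(n), count_trees(n))
})

test_that("enumerated trees are pairwise non-isomorphic and structurally valid", {
    for (n in c(4L, 5L)) {
        trees <- enumerate_trees(n)
        codes <- vapply(trees, canonical_code, character(1))
        expect_length(unique(codes), count_trees(n))
        for (tr in trees) {
            expect_equal(nrow(tr$edges), 2L * n - 1L)
            ind <- arcnets:::.indeg(tr$edges, tr$nv)
            outd <- arcnets:::.outdeg(tr$edges, tr$nv)
            expect_true(all(ind[seq_len(n)] == 1L & outd[seq_len(n)] == 0L)) # leaves
            expect_identical(c(ind[n + 1L], outd[n + 1L]), c(0L, 1L))        # root
            internal <- setdiff(seq_len(tr$nv), c(seq_len(n), n + 1L))
            expect_true(all(ind[internal] == 1L & outd[internal] == 2L))
        }
    }
})

test_that("random_tree is uniform over the 15 trees on 4 leaves", {
    set.seed(42)
    codes_all <- vapply(enumerate_trees(4), canonical_code, character(1))
    draws <- vapply(seq_len(30000), function(i) canonical_code(random_tree(4)),
                    character(1))
    tab <- table(factor(draws, levels = codes_all))
    expect_equal(sum(tab), 30000)
    expect_true(all(tab > 0))
    p <- chisq.test(tab, p = rep(1 / 15, 15))$p.value
    expect_gt(p, 0.001)
})

test_that("random_tree is deterministic given a seed", {
    a <- random_tree(10, seed = 123)
    b <- random_tree(10, seed = 123)
    expect_identical(a, b)
    expect_false(identical(random_tree(10, seed = 124)$edges, a$edges))
})

test_that("Newick round trips preserve the tree, exhaustively at n = 4", {
    expect_equal(write_newick(read_newick("(1,2);")), "(1,2);")
    expect_equal(write_newick(read_newick("((1,2),(3,4));")), "((1,2),(3,4));")
    expect_equal(write_newick(read_newick("1;")), "1;")
    for (tr in enumerate_trees(4)) {
        s <- write_newick(tr)
        expect_identical(canonical_code(read_newick(s)), canonical_code(tr))
    }
})

test_that("the Newick dialect round-trips through ape", {
    for (tr in enumerate_trees(4)) {
        s <- write_newick(tr)
        ap <- ape::read.tree(text = s)
        expect_equal(ape::Ntip(ap), 4L)
        s2 <- ape::write.tree(ap)
        expect_identical(canonical_code(read_newick(s2)), canonical_code(tr))
    }
})

test_that("malformed Newick raises positional parse errors", {
    expect_error(read_newick("((1,2);"), "position")
    expect_error(read_newick("(1,2)"), "position")
    expect_error(read_newick("(1,x);"), "position")
    expect_error(read_newick("(1,1);"), "labels")
    expect_error(read_newick("(1,3);"), "labels")
    expect_error(read_newick("((1,2,3),4);"), "2 children")
})
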