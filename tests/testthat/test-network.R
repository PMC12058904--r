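# Classification of decoration graphs, structural queries, canonical codes,
# and eNewick I/O.

test_that("decoration graphs satisfy the degree invariants, exhaustively at (4,1)", {
    for (net in enumerate_networks(4, 1)) {
        ind <- arcnets:::.indeg(net$edges, net$nv)
        outd <- arcnets:::.outdeg(net$edges, net$nv)
        n <- net$n
        expect_true(all(ind[seq_len(n)] == 1L & outd[seq_len(n)] == 0L))
        expect_identical(c(ind[n + 1L], outd[n + 1L]), c(0L, 1L))
        expect_identical(unname(ind[9L]), 1L)   # p1: tree vertex after arc
        expect_identical(unname(outd[9L]), 2L)
        expect_identical(unname(ind[10L]), 2L)  # p'1: reticulation
        expect_identical(unname(outd[10L]), 1L)
        expect_equal(sum(ind >= 2L), 1L)
    }
})

test_that("an arc to an ancestor of its source forces a directed cycle", {
    expect_true(is_acyclic(as_network(cherry2())))
    expect_false(is_acyclic(as_network(cherry_dec_cycle())))
    expect_error(is_tree_child(as_network(cherry_dec_cycle())), "cyclic")
    expect_error(shortcuts(as_network(cherry_dec_cycle())), "cyclic")
    expect_error(temporal_ranking(as_network(cherry_dec_cycle())), "cyclic")
})

test_that("tree-child and shortcut detection match their definitions", {
    tr <- as_network(balanced4())
    expect_true(is_tree_child(tr))
    expect_equal(nrow(shortcuts(tr)), 0L)
    expect_true(is_normal(tr))

    two_retics <- as_network(cherry_dec_two_retic_children())
    expect_true(is_acyclic(two_retics))
    expect_false(is_tree_child(two_retics))
    expect_equal(classify_network(two_retics), "not_tree_child")

    par <- as_network(cherry_dec_stacked()) # arc parallel to tree edge 5->6
    expect_true(is_acyclic(par))
    sc <- shortcuts(par)
    expect_true(nrow(sc) >= 1L)
    expect_true(any(sc[, 1] == 5L & sc[, 2] == 6L))
    expect_false(is_normal(par))
})

test_that("the compiled classifier agrees with an independent igraph-based one at (4,1)", {
    nets <- enumerate_networks(4, 1)
    mine <- vapply(nets, classify_network, character(1))
    ref <- vapply(nets, ref_classify, character(1))
    expect_identical(mine, ref)
    # class totals match the exhaustive census
    cs <- run_census(4, 1)
    expect_equal(as.vector(table(factor(mine, levels = names(cs$counts)))),
                 as.vector(cs$counts))
    # normal outcomes: acyclic & tree-child & shortcut-free, 108 = 2^1 * 54
    expect_equal(sum(mine %in% c("normal_not_hyb", "hybridization")), 108)
})

test_that("temporal rankings exist for trees and survive the literal re-check", {
    tr <- as_network(caterpillar4())
    dates <- temporal_ranking(tr)
    expect_false(is.null(dates))
    expect_true(validate_temporal_ranking(tr, dates))
    expect_equal(classify_network(tr), "hybridization")
})

test_that("every temporal ranking among (4,2) normal networks passes the literal re-check", {
    cs <- run_census(4, 2, reps = TRUE)
    n_ranked <- 0L
    for (net in cs$reps) {
        dates <- temporal_ranking(net)
        if (!is.null(dates)) {
            n_ranked <- n_ranked + 1L
            expect_true(validate_temporal_ranking(net, dates))
        }
    }
    expect_equal(n_ranked, 36L) # H_{4,2}
})

test_that("collinearity follows the distinct-heads convention", {
    expect_equal(nrow(collinear_pairs(as_network(balanced4()))), 0L)
    # k = 1: only one reticulation, the two reticulation edges share a head
    d <- cherry_dec_sides()
    expect_equal(nrow(collinear_pairs(as_network(d))), 0L)
})

test_that("normal networks without collinear reticulation edges are temporal (exhaustive n <= 5, k <= 2)", {
    for (nk in list(c(3, 1), c(4, 1), c(5, 1), c(4, 2), c(5, 2))) {
        cs <- run_census(nk[1], nk[2], reps = TRUE)
        for (i in seq_along(cs$reps)) {
            net <- cs$reps[[i]]
            no_collinear <- nrow(collinear_pairs(net)) == 0L
            has_ranking <- !is.null(temporal_ranking(net))
            if (no_collinear) expect_true(has_ranking)
            # ranking status must agree with the census label
            expect_equal(has_ranking, cs$rep_is_hyb[i])
        }
    }
})

test_that("a collinear pair is reported when tree paths connect two reticulations", {
    cs <- run_census(4, 2, reps = TRUE)
    non_hyb <- cs$reps[!cs$rep_is_hyb]
    # normal-but-not-temporal networks here must contain a collinear pair
    for (net in non_hyb) expect_gt(nrow(collinear_pairs(net)), 0L)
})

test_that("displayed trees: 2^k distinct trees, base tree always among them", {
    t0 <- balanced4()
    d0 <- displayed_trees(as_network(t0))
    expect_length(d0, 1L)
    expect_identical(canonical_code(d0[[1]]), canonical_code(t0))

    for (tr in enumerate_trees(4)) {
        for (d in enumerate_decorations(tr, 1)) {
            net <- as_network(d)
            if (!is_acyclic(net) || !is_normal(net)) next
            shown <- displayed_trees(net)
            expect_length(shown, 2L)
            codes <- vapply(shown, canonical_code, character(1))
            expect_true(canonical_code(tr) %in% codes)
        }
    }
    expect_error(displayed_trees(as_network(cherry_dec_stacked())), "normal")
})

test_that("every normal network in the (4,2) and (5,2) censuses displays exactly 2^k trees", {
    for (nk in list(c(4, 2), c(5, 2))) {
        cs <- run_census(nk[1], nk[2], reps = TRUE)
        sizes <- vapply(cs$reps, function(net) length(displayed_trees(net)), integer(1))
        expect_true(all(sizes == 2L^nk[2]))
    }
})

test_that("canonical codes certify label-preserving isomorphism (igraph cross-check)", {
    cs <- run_census(4, 1, reps = TRUE)
    reps <- cs$reps[1:12]
    codes <- vapply(reps, canonical_code, character(1))
    for (a in seq_along(reps)) {
        for (b in seq_len(a)) {
            expect_identical(codes[a] == codes[b], ref_isomorphic(reps[[a]], reps[[b]]),
                             info = sprintf("pair (%d, %d)", a, b))
        }
    }
})

test_that("two decorations of one network share a code; leaf relabeling changes it", {
    # the 108 normal (4,1) decorated trees collapse to the 54 networks
    nets <- Filter(function(net) is_acyclic(net) && is_normal(net),
                   enumerate_networks(4, 1))
    codes <- vapply(nets, canonical_code, character(1))
    expect_length(codes, 108L)
    expect_length(unique(codes), 54L)
    expect_true(all(table(codes) == 2L))

    cat4 <- caterpillar4() # asymmetric: swapping leaves 1 and 3 changes the code
    swapped <- cat4
    swapped$edges[] <- ifelse(swapped$edges == 1L, 99L, swapped$edges)
    swapped$edges[] <- ifelse(swapped$edges == 3L, 1L, swapped$edges)
    swapped$edges[] <- ifelse(swapped$edges == 99L, 3L, swapped$edges)
    expect_false(canonical_code(swapped) == canonical_code(cat4))
    # unlabeled codes agree: same shape
    expect_identical(canonical_code(swapped, labeled = FALSE),
                     canonical_code(cat4, labeled = FALSE))
})

test_that("eNewick round trips preserve the canonical code for all normal (4,2) networks", {
    expect_equal(write_enewick(as_network(balanced4())), "((1,2),(3,4));")
    cs <- run_census(4, 2, reps = TRUE)
    for (net in cs$reps) {
        s <- write_enewick(net)
        expect_equal(length(gregexpr("#H1", s, fixed = TRUE)[[1]]) >= 2, TRUE)
        back <- read_enewick(s)
        expect_identical(canonical_code(back), canonical_code(net))
    }
})

test_that("a single-reticulation network writes exactly one #H1 tag, twice", {
    cs <- run_census(4, 1, reps = TRUE)
    s <- write_enewick(cs$reps[[1]])
    expect_equal(lengths(regmatches(s, gregexpr("#H1", s, fixed = TRUE))), 2L)
    expect_false(grepl("#H2", s, fixed = TRUE))
})

test_that("eNewick parse errors are informative", {
    expect_error(read_enewick("((1)#H1,2);"), "#H1")
    expect_error(read_enewick("(1,2,3);"), "not valid")
    expect_error(read_newick("((1)#H1,#H1,2);"), "plain Newick")
})
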