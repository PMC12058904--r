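# arcnets

Phylogenetic networks from arc-decorated trees: construction, exhaustive
enumeration, classification, exact counting, and Monte Carlo exploration.

## The problem

Rooted binary phylogenetic networks generalize phylogenetic trees by allowing
reticulation vertices (in-degree 2, out-degree 1) that model hybridization and
other reticulate events. One natural way to produce such a network is to take
a rooted binary tree *T* on leaf set {1, …, n} (with an ancestral root edge),
subdivide its edges with *k* ordered pairs of points (p_i, p′_i) placed
sequentially, and add an arc p_i → p′_i for each pair. The resulting directed
graph G((T_k, ω_k)) may

* contain a directed cycle (then it is not a network at all),
* be a network that fails the *tree-child* condition (some vertex has only
  reticulation children) or contains a *shortcut* (an edge (u, v) with another
  directed u→v path), or
* be a *normal* network (tree-child, no shortcut), possibly even a
  *hybridization network* — a tree-child network admitting dates T(v) that
  increase strictly along tree edges and are equal across each reticulation
  and its two parents.

`arcnets` is for combinatorialists and mathematical phylogeneticists who want
to enumerate, classify, count and sample these objects exactly.

## The core quantities

With r_n = (2n−3)!! trees on n leaves, a fixed tree admits

    |S(T,k)| = (2n−1)(2n)⋯(2n+2k−2) / k!

k-fold decorations, and |S(n,k)| = |S(T,k)| · r_n in total. Every normal
network with k reticulations displays exactly 2^k distinct trees, so the
number of decorated trees whose graph is normal is 2^k · N_{n,k}, where
N_{n,k} counts distinct normal networks up to label-preserving isomorphism.
The package reproduces the exact small-parameter censuses

    N_{4,1} = H_{4,1} = 54,   N_{4,2} = 48,   H_{4,2} = 36,   H_{5,2} = 1890,

the closed forms for H_{n,1}, H_{n,2} and N_{n,2}, their exponential
generating functions over exact rationals (e.g. H_1(z) = ½ r³/(1−r)³ with
r(z) = 1 − √(1−2z)), and the log-space asymptotics
N_{n,k} ~ (2^{k−1}√2 / k!) (2/e)^n n^{n+2k−1}.

## Worked example

```r
library(arcnets)
cs <- run_census(4, 2, shapes = TRUE)
print(cs)
```

```
Census of 2-fold decorated trees on [4]: 37,800 decorated trees
               count
cyclic         21045
not_tree_child 11667
shortcut        4896
normal_not_hyb    48
hybridization    144
normal (S_no)    192
distinct normal networks N = 48, distinct hybridization networks H = 36
unlabeled shape orbit sizes: 24, 12, 12
by ell (non-leaf subdivision vertices):
    0     1     2     3
  180  5400 20520 11700
```

Of the 37,800 two-fold decorated trees on four leaves, 21,045 produce a
cyclic graph and 16,563 a network; 192 = 2²·48 of them are normal, collapsing
to 48 distinct normal networks of which 36 admit a temporal ranking
(hybridization networks). The 48 fall into three unlabeled shapes with orbit
sizes 24, 12 and 12. The `ell` row stratifies decorations by the number of
non-leaf subdivision vertices of the induced subdivision tree, which always
has 4k−2−ell edges.

Individual networks are first-class objects:

```r
net <- run_census(4, 1, reps = TRUE)$reps[[1]]
write_enewick(net)        # "((((1)#H1,2),(#H1,3)),4);"
temporal_ranking(net)     # integer dates per vertex, e.g. 5 6 7 2 0 4 3 1 4 4
length(displayed_trees(net))  # 2 = 2^1
```

Closed forms, series and sampling:

```r
H2_exact(6)                      # 66960
egf_coeff(H2_series(12, "cases"), 6)  # 66960, from the exact rational EGF
estimate_proportions(20, 2, 20000, seed = 1)$p_normal  # P(normal) with Wilson CI
```

A thin command-line wrapper (`inst/cli/arcnets`) exposes the same pipelines:
`arcnets census --n 4 --k 2 --shapes --out report.json`.

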