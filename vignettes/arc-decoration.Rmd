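---
title: "Counting normal and hybridization networks by decorating trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting normal and hybridization networks by decorating trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcnets)
```

## The model

A (binary) phylogenetic network on leaf set $[n]=\{1,\dots,n\}$ is a rooted
directed acyclic graph whose leaves (out-degree 0) are bijectively labeled by
$[n]$, whose other vertices are tree vertices (in 1, out 2) or reticulation
vertices (in 2, out 1), and whose root has in-degree 0 and out-degree 1 — it
sits atop an *ancestral root edge*. Edges into a reticulation are
reticulation edges; all others are tree edges. Three nested classes matter
here:

* **tree-child**: every non-leaf vertex has at least one child that is a
  leaf or tree vertex;
* **normal**: tree-child with no *shortcut* (an edge $(u,v)$ with a second
  directed $u \to v$ path);
* **hybridization** (temporal): tree-child and admitting dates $T(v)$ with
  $T(u) < T(v)$ along every tree edge and $T(u)=T(v)=T(w)$ across every
  reticulation $v$ with parents $u,w$. Every hybridization network is
  normal, but not conversely.

The package studies the *decoration* construction: take a rooted binary tree
$T$ on $[n]$ (the root edge counts, so $T$ has $2n-1$ edges), and insert $k$
ordered pairs of subdivision points sequentially — $p_i$ on any edge of the
current subdivided tree, then $p_i'$ on any edge of the result, the two
half-edges just created included. Adding the arcs $p_i \to p_i'$ yields the
directed graph $G$. Because each decorated tree arises from exactly $k!$
insertion orders of its pairs, a fixed tree has
$|S(T,k)| = (2n-1)(2n)\cdots(2n+2k-2)/k!$ decorations, and sequential
uniform placement is exactly uniform over them — this single fact powers
both the census (enumerate raw sequences, divide tallies by $k!$, with exact
divisibility asserted) and the Monte Carlo sampler.

## Classification

`classify_network()` assigns one of five mutually exclusive labels in a
fixed precedence order: `cyclic` (a topological sort fails); otherwise
`not_tree_child`; otherwise `shortcut`; otherwise the graph is normal and
the temporal test splits `hybridization` from `normal_not_hyb`. Two
conventions deserve note:

* **Multigraphs.** When $p_i'$ lands on a half-edge adjacent to $p_i$, the
  arc is parallel to a tree edge. We keep the parallel pair (the graph is a
  multigraph) and the arc is a shortcut, so such graphs are never normal;
  a vertex whose two parallel edges both point at one reticulation also
  fails the tree-child condition. Either way they stay outside the normal
  class, which keeps the five labels an exhaustive partition of all
  decorated trees.
* **Precedence of the fine labels.** `not_tree_child` is tested before
  `shortcut`; the coarse non-normal-network class is their union, so the
  precedence affects only the fine tabulation, which is kept because the
  two failure modes scale differently and are worth inspecting separately.

The temporal test merges each reticulation with its two parents
(union-find over reticulation edges), rejects if a tree edge joins two
vertices of one class, and otherwise topologically orders the quotient.
When dates are requested the order is made deterministic by always releasing
the available class with the smallest member vertex; among valid rankings
this is an arbitrary but reproducible choice. Every ranking the package
returns can be re-checked literally, edge by edge, with
`validate_temporal_ranking()`, which shares no code with the construction.

## The induced subdivision tree

The minimal subtree of the subdivided tree $T_k$ spanning the $2k$
subdivision points, with pass-through binary vertices of $T$ suppressed, has
vertex set = subdivision points $\cup$ branch points. With $\ell$ the number
of subdivision points that are not leaves of this subtree (a unary root
counts), the subtree has exactly $4k-2-\ell$ edges. The census recomputes
$\ell$ for every decoration and *asserts* the edge identity as it streams —
a violation aborts the run — and the R-level
`induced_subdivision_tree()` re-derives both quantities independently for
spot checks and the stratified `by_ell` table. Decorations whose graph is
cyclic always have $\ell \ge 1$; the census counts an explicit
`cyclic & ell = 0` cell that must stay empty.

## Canonical codes and deduplication

Networks are compared by label-preserving directed-graph isomorphism. The
canonical code is computed by colour refinement (initial colours: leaf
labels, or a single leaf colour for unlabeled "shape" codes) followed by
individualization with full backtracking: every vertex of the first
non-singleton colour class is individualized in turn and the lexicographic
minimum over all resulting discrete codes is kept. This is sound — equal
codes certify an isomorphism and vice versa — unlike hash-based schemes;
the test suite cross-checks it pairwise against VF2 isomorphism with vertex
colours from an independent graph library.

Decorated trees themselves (not their graphs) are deduplicated by the same
engine run on the subdivided tree with the arcs carried as a second edge
colour: a leaf-labeled binary tree has no nontrivial automorphism, so code
equality is exactly equality of configurations, and the enumeration's
raw-sequence-to-distinct ratio of $k!$ is itself a tested invariant. The
deduplication of a network's $2^k$ decorated-tree preimages is what turns
class counts into network counts: $|S_{no}(n,k)| = 2^k N_{n,k}$, because a
normal network with $k$ reticulations displays exactly $2^k$ distinct trees.

## Collinearity and the temporal sufficient condition

Two reticulation edges are *collinear* when an endpoint of one reaches an
endpoint of the other along tree edges only. A normal network from the
decoration construction with no collinear reticulation edges is always a
hybridization network. The definition leaves two edge cases open, which we
resolve as follows and verify exhaustively: only pairs with *distinct* head
reticulations are eligible (the two edges into one reticulation share a
head, and admitting them would make every $k \ge 1$ network collinear,
voiding the implication), and tree paths of length zero count (sharing a
vertex qualifies). Under this convention the implication
*no collinear pair ⇒ temporal ranking exists* holds with zero exceptions
over every normal network with $n \le 5$, $k \le 2$, which is the safety
net for the convention.

## Exact arithmetic

The closed-form counts — $r_n=(2n-3)!!$ evaluated through
$(2n-2)!/(2^{n-1}(n-1)!)$, the decoration products, and

$$H_{n,1} = \tfrac12\big[(2n{+}1)!! + 3(2n{-}1)!!\big] - 3\,n!\,2^{n-1},$$
$$H_{n,2} = (2n{-}1)!!\,(n^3+9n^2-16n-12) - 3\,n!\,2^n(n^2-4),$$
$$N_{n,2} = \tfrac13(2n{-}1)!!\,(3n-4)(n^2+11n+6) - n!\,2^n(3n^2+2n-8)$$

— are computed over arbitrary-precision integers written for this package
(sign + magnitude in base $2^{32}$, binary gcd, bit-serial division); all
internal divisions (by 2, by 3, by $k!$) are asserted exact. Values are
returned as doubles while exactly representable and as decimal strings
beyond $2^{53}$; `log = TRUE` gives the exact natural logarithm from the
big integer, which is what the large-$n$ ratio checks use.

The series module works over exact big rationals. $r(z) = 1-\sqrt{1-2z}$ is
built by the term-by-term square-root recurrence
$s_n = (a_n - \sum_{i=1}^{n-1} s_i s_{n-i})/2$, whose correctness is pinned
by the squaring identity $s^2 = 1-2z$ holding exactly at every order.
$H_1(z) = \tfrac12 r^3/(1-r)^3$, and $H_2(z)$ is assembled three independent
ways — the root bridgeless-component case decomposition with the fixed point
$H_2 = H_2 r + \dots$ solved by dividing through by $1-r$; the explicitly
solved expression; and the partial-fraction expansion in powers of
$(1-r)^{-1}$ with coefficients $\tfrac{15}{8}, -6, \tfrac{27}{8}, 9,
-\tfrac{123}{8}, 9, -\tfrac{15}{8}$ — which must agree coefficient-wise, so
a transcription slip in any one form is caught. Truncation order is capped
at 64 by default: coefficients grow super-exponentially but stay cheap as
big rationals, and every identity the package asserts is visible well below
that order.

Asymptotics ($|S(n,k)|$, $N_{n,k}$, $N_{n,2}-H_{n,2}$) are evaluated in
log-space only, because $(2/e)^n n^{n+2k-1}$ overflows doubles near
$n \approx 120$; convergence is always assessed through relative-error
ladders (e.g. $n = 50, 100, 200, 400$), never absolute tolerances.

## Exhaustive ranges and problem sizes

The census streams placement sequences in compiled code and retains only
the canonical codes (plus one representative) of normal outcomes, so memory
follows the number of distinct normal networks — e.g. the $(5,2)$ universe
has 623,700 decorated trees but only 9,240 normal outcomes and 2,310 codes.
The supported exhaustive range is $n \le 8$ for $k=0$, $n \le 6$ for $k=1$,
$n \le 5$ for $k=2$; larger requests are refused with the exact universe
size. These are the sizes at which every structural property is verified
exhaustively; the test suite additionally checks the subdivision-tree edge
identity on $10^4$ random decorations at $n=20, k=5$, and the Monte Carlo
trend at $n$ up to 80.

## Monte Carlo design

`estimate_proportions()` draws uniform decorated trees (uniform tree by
sequential leaf insertion, then uniform sequential point placement — the
exact process whose outcomes the censuses count), classifies each, and
reports Wilson score intervals. Wilson rather than Wald because the
proportions of interest are extreme on both ends: the normal fraction is
tiny at small $n$ and approaches 1 as $n$ grows at fixed $k$. Wherever an
exhaustive census exists the exact proportion is known (e.g.
$192/37{,}800$ at $(4,2)$), and interval coverage is itself tested across
seeded replicates. All randomness flows through R's RNG — a seed argument
calls `set.seed()` — so every report is reproducible bit for bit.

What the sampler emulates is exactly the uniform arc-placement model, and
nothing more: it says how often *this construction* yields normal or
temporal networks, not how often empirical phylogenies do. Real data
involve non-uniform tree shapes, correlated reticulation placement, and
far larger reticulation numbers relative to $n$; none of that is modeled,
and passing tests make no claim about it. Likewise, networks with many
reticulations (the regime $k \sim n$) behave qualitatively differently and
are outside the scope of both the construction and the asymptotics
explored here, which concern fixed or slowly growing $k$.

## Known limitations

* Closed forms and series are implemented for $k \le 2$ only; no closed
  form for $k \ge 3$ is provided (none is available in this framework),
  though the census and sampler handle any $k$ within their ranges.
* The canonical-code backtracking is exponential in the worst case over
  pathological colour-refinement ties; on the near-tree graphs produced
  here the refinement is almost always discrete after one or two rounds.
* eNewick I/O covers the binary, single-root networks this package
  produces; it is not a general-purpose eNewick implementation.
* `displayed_trees()` asserts its $2^k$ guarantee only for normal
  networks and refuses other inputs rather than guessing semantics.
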