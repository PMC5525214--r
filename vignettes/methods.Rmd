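---
title: "Methods: exact phylogeny-aware search of microbiome profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact phylogeny-aware search of microbiome profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsearch)
```

## The problem

Given a 16S rRNA community profile — a sparse vector of OTU abundances over
a fixed reference phylogeny — we want every database sample within a chosen
weighted-UniFrac radius of the query, ranked and placed in context. Weighted
UniFrac is the field's standard phylogeny-aware beta-diversity measure; for
relative abundances it equals the Earth Mover Distance (EMD) with tree path
length as the ground distance, and it is a true metric. That opens the door
to exact metric-space indexes: the search can prune most of the database by
the triangle inequality without ever returning a false negative, unlike
heuristic indexes keyed on (for example) a sample's most abundant phyla.

## The distance kernel

`emd_unifrac_sparse()` computes weighted UniFrac by bottom-up mass
propagation. Abundance differences between the two profiles sit at the
leaves; processing levels deepest-first, each node adds
|accumulated unbalanced mass| x (branch length to its parent) to the
distance and passes the residual up iff it is non-zero. Only ancestors of
leaves where the profiles actually differ are ever touched, so for sparse
profiles the traversal visits a small fraction of the tree; the
`visited_nodes` counter exposes this economy. Two independent routes guard
the kernel: a dense variant that propagates through every node, and the
per-branch sum over "fraction of each community below the branch". All
three agree to 1e-9 on randomized fixtures, and the sparse traversal is
verified against the union-of-ancestor-paths bound.

Numerical choices: the value is the *raw* EMD on relative abundances (no
normalization by tree depth) — that is the quantity that is a metric and
that the indexes require; residual masses below 1e-12 are treated as
balanced and not propagated, preventing floating-point dust from forcing a
full-tree walk; inputs must sum to one within 1e-9, and unknown OTU labels
are an error rather than silently dropped mass. The root carries no branch
and never contributes. Multifurcations are supported (reference phylogenies
contain polytomies); nothing assumes binary trees.

Bray-Curtis dissimilarity is provided for the coarse, non-phylogenetic
route. It is computed on (optionally pairwise-rarefied) counts — the
classical formulation — and is *not* a metric, which is exactly why the
coarse route searches a bounded set of representatives instead of using the
metric indexes.

## Exact search structures

Two index structures support exact range search, both recording every true
distance evaluation they perform:

* **GNAT** (geometric near-neighbor access tree): each node picks
  `branching` pivots greedily (max-min separation from a seeded candidate
  sample of 3 x branching points), assigns the remaining points to their
  nearest pivot, and stores exact min/max distance ranges from each pivot
  to each sibling domain. A child is pruned when some evaluated pivot's
  query distance interval cannot intersect the child's stored range.
  Build cost is subquadratic; search recall is 100% by construction.
  Defaults (branching 8, leaf bucket 16, candidate pool 3 x branching) are
  our own: the underlying algorithm does not fix them, and these give
  balanced trees at the database sizes the tests use.
* **AESA**: precomputes the full pairwise matrix (exactly `choose(n, 2)`
  evaluations — the heavy precalculation that pays off when queries are
  frequent), then repeatedly evaluates the candidate with the smallest
  lower bound `max_p |d(q,p) - d(p,s)|`, eliminating everything whose
  bound exceeds the radius. Per query it typically needs far fewer true
  evaluations than a linear scan.

Everything ties deterministically by ascending sample id. A brute-force
linear scan is kept as the oracle; the test suite asserts hit-set equality
of all three on randomized databases at radii 0.1-0.4.

## Contextualization

Per-query range searches (default radius 0.3, a radius at which an
appreciable share of database pairs qualify while pruning stays effective)
record their evaluations. The context set M' keeps database samples that
were compared against *every* query — so the composed matrix has no missing
cells — and, among those, samples ranking within the top k (default 20) of
at least one query, with the ranking computed inside that intersection.
Ranking within the intersection (rather than over all evaluated samples) is
a deliberate choice where the procedure could be read either way: it
guarantees completeness of the context-by-query block by construction.

The full matrix over M' and the queries is assembled block-wise:
context-context cells come from the precomputed database store,
context-query cells from the recorded search evaluations, query-query
cells from direct kernel calls. PCoA is classical scaling
(`stats::cmdscale` on the double-centered squared distances); negative
eigenvalues — expected, since UniFrac matrices need not be Euclidean —
are dropped with a warning. Clustering is UPGMA (`stats::hclust`,
average linkage) with merge heights reported on the ultrametric scale
(half the cophenetic distance), exported as newick.

## Significance and the coarse route

The empirical p-value of a match at distance d is the fraction of all
database pair distances strictly below d. For speed, pair distances are
binned into 10,000 equal-width bins over [0, max]; the lookup reads the
cumulative count at the lower edge of d's bin, a conservative convention
that is exact at bin edges and within one bin's mass elsewhere (verified
against direct counting).

The coarse route (`run_type2()`) restricts the database to an ecosystem
filter, cuts an average-linkage clustering of the precomputed distances
into at most 1000 clusters, and represents each cluster by its medoid
(minimum summed within-cluster distance; ties by id). The filter is applied
*before* clustering so that a small filtered pool is returned whole.
Queries are then ranked against representatives by Bray-Curtis and
contextualized together with them.

## Preprocessing

Copy-number correction divides each OTU's abundance by its 16S operon
count; OTUs missing from the table default to 1 and are reported.
Pairwise adaptive rarefaction subsamples the deeper member of a compared
pair, without replacement, to the shallower member's depth; its RNG stream
is derived from the job seed plus the (sorted) pair of sample ids, so
results do not depend on comparison order. Because correction produces
fractional counts, rarefaction refuses non-integer input: rarefy first,
then correct — the pipeline enforces this ordering through that
precondition. At the engine level the flags apply to the *query* profiles
(database profiles are taken as already normalized when the precomputed
matrix was built); the multi-query phylogenetic route rarefies all queries
to their common minimum depth, while the Bray-Curtis route applies true
per-pair rarefaction.

Query-count limits are 1-10 samples per submission for GNAT and up to 100
for AESA, enforced at the command line and overridable programmatically.

## The synthetic fixture generator

`random_tree()` draws a random binary coalescent topology with exponential
coalescent branch lengths, rescaled to unit root-to-tip height so that
community distances land on the scale the radii 0.1-0.4 address.
`random_profiles()` gives each ecosystem a random leaf subset of expected
size `sparsity * n_leaves` (default sparsity 5%, matching the sparse,
closed-reference profiles the search is designed for) and a Dirichlet
center over it; each sample draws proportions from a Dirichlet around its
ecosystem's center (concentration `separability * support`; the default
separability 5 yields within-ecosystem UniFrac distances of roughly
0.05-0.2 against between-ecosystem distances of roughly 0.3-0.7 — distinct
but overlapping, as in real environmental data) and then multinomial
counts at Poisson depth (mean 2000 reads, an ordinary rarefied 16S depth).
Taxonomy is derived by clade cuts (a leaf's label at each rank is its
ancestor at a rank-specific depth), so lineages nest consistently with the
tree; copy numbers are uniform on 1..10. Everything is a pure function of
the seed.

What the generator does *not* emulate: sequencing noise, chimeras,
compositional artifacts of amplification, realistic phylum-level taxon
frequencies, or databases with tens of thousands of samples. Passing tests
therefore demonstrate algorithmic correctness (exactness, metric behavior,
bound compliance) at desk scale, not field-scale performance numbers;
published node-visit percentages and absolute pair counts from
production-size databases are out of reach by design, and the suite asserts
the underlying mechanisms instead.

## Problem sizes used

The default verification runs use: 1000 random (tree, profile-pair)
fixtures with trees up to 200 leaves for kernel equivalence; a 500-sample,
256-leaf database with 12 held-out queries at radii 0.1-0.4 for index
exactness; a 400-leaf tree at 5% sparsity for traversal economy; and a
24-sample database for the p-value comparison. These sizes exercise every
code path (multi-level GNAT recursion, AESA elimination, histogram edge
cases) while keeping the whole suite comfortably reproducible on a laptop.

## Known limitations

* The on-disk distance store is a dense plain-text matrix; fine for the
  fixture scale, unsuitable for 10^4+ samples.
* Bray-Curtis p-values are computed over representative pairs only.
* The phylogenetic route assumes query OTUs are leaves of the reference
  tree (closed-reference picking); there is no fallback placement.
* `run_type1()` recomputes context PCoA/clustering per call; indexes can
  be reused across calls but the context is query-specific by design.
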