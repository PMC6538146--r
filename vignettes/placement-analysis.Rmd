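---
title: "Analyzing phylogenetic placement data with placemass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing phylogenetic placement data with placemass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placemass)
```

## The data model

Phylogenetic placement maps each anonymous query sequence (QS) of an
environmental sample onto the branches of a fixed reference tree (RT).
Every candidate branch receives a *likelihood weight ratio* (LWR), the
probability that the sequence belongs on that branch; the LWRs of one
query sum to 1 over all branches. `placemass` interprets these LWRs as
point masses at their optimized positions on the edges: a fully placed
query contributes one unit of mass (times its multiplicity) to the tree.
Everything in the package is built on this mass interpretation.

A `place_tree` wraps an `ape::phylo` object together with the integer
edge numbers of the jplace format. Trees must be strictly bifurcating; an
unrooted input keeps its top-level trifurcation as the "root". Edges are
kept in preorder, which is the canonical column order of every per-edge
vector and matrix the package produces — matrices are therefore
comparable across runs and functions.

A `place_sample` holds the placements of one sample. `read_jplace()`
accepts jplace versions 1–3, maps fields by name, reads both the `{}` and
`[]` edge-number dialects and both the `n` and `nm` naming conventions,
derives LWRs from raw `likelihood` scores by a numerically stable softmax
when needed, and converts `distal_length` to proximal positions. Pqueries
whose LWRs sum to less than 1 are kept as-is by default: the missing mass
is the mass of discarded unlikely placements and is meaningful;
`renormalize = TRUE` rescales per query. Pendant lengths are read and
written but never used in computations — mass lives on RT edges only.

## Masses, imbalances, binning, squashing

`edge_masses()` accumulates `multiplicity * LWR` per edge; the total of a
fully placed sample equals its number of queries. Because library sizes
vary by orders of magnitude, most analyses use `normalize_masses()`,
which scales a sample to unit mass (relative abundances — the closure of
the composition, with all ensuing compositional caveats).

The *imbalance* of an edge is the mass on its root side minus the mass on
its non-root side, ignoring the edge's own mass. It summarizes whole
clades rather than single edges and implicitly encodes the tree topology.
On a unit-mass sample every imbalance lies in [-1, 1]. The imbalance of a
leaf edge is just `1 - edge mass` and carries no clade information, so
leaf edges are dropped by default (`include_tips = TRUE` keeps them).
`edge_imbalances()` runs in O(m) with two tree passes; the test suite
checks it against an O(m^2) brute-force re-summation.

*Branch binning* (`bin_masses()`) discretizes the mass points of each
edge into `b` equal intervals, accumulating each point into the bin with
the nearest center; ties at exact midpoints go to the lower-index bin, a
deterministic convention. `b = 1` collapses an edge to its edge mass.
Binning conserves per-edge masses exactly and trades a negligible loss in
KR-distance accuracy for fewer mass points.

*Squashing* (`squash()`) forms the weighted average of several mass
distributions on the same tree — the representation of a cluster of
samples as a single mass distribution.

## The KR distance

`kr_distance()` computes the order-1 phylogenetic
Kantorovich–Rubinstein (earth mover) distance between two unit-mass
distributions, with the tree-path metric as ground distance: the least
total mass-times-displacement needed to turn one distribution into the
other. Because the ground space is a tree, the optimal transport has a
closed form: accumulate the signed mass difference towards the root and
charge every infinitesimal segment `|net mass crossing it| * length`.
This is a single postorder pass, O(m + P) per pair after sorting the P
mass points once. The suite verifies the metric axioms and checks the
pass against an exact linear-programming transport solution on small
trees. Samples with unequal totals (beyond 1e-6) are rejected rather than
silently rescaled; `renormalize = TRUE` opts into rescaling with a
warning.

## Clustering

`squash_clustering()` is agglomerative clustering in which the merge of
two clusters is the member-count-weighted squash of their mass
distributions, and the pair with the smallest KR distance merges first
(ties broken by lexicographic cluster index for determinism). Each child
of a merge node receives half the merge distance as branch length, so
tips are samples and path lengths reflect KR distances between clusters.

`phylogenetic_kmeans()` is Lloyd's algorithm with the KR distance for
assignment and the squash for the centroid update; `imbalance_kmeans()`
is standard Euclidean Lloyd k-means on rows of the imbalance matrix, and
is orders of magnitude faster because it needs no tree traversals. Both
variants share one Lloyd loop: k-means++ seeding (selection probability
proportional to the squared distance to the nearest selected sample;
uniform seeding behind `init = "random"`), a `max_iter` cap of 100
(convergence is usually much earlier), and empty-cluster repair — the
sample furthest from its centroid in the highest-variance cluster is
moved into each empty cluster, ties towards the lowest sample index. A
fixed seed yields a bit-identical clustering. `elbow_curve()` reports the
mean squared distance to the assigned centroids over a range of k.

## Balances: a placement ILR transform

Where imbalances contrast the two sides of an edge by a *difference of
sums*, balances contrast them by a *log-ratio of geometric means* — the
isometric log-ratio (ILR) coordinate associated with the bipartition.
For disjoint edge sets R and S,

    y*(R, S) = sqrt(nu_R * nu_S / (nu_R + nu_S)) * log( gm(y_R, p_R) / gm(y_S, p_S) )

with `nu_R = sum(p_R)`, `gm` the weighted geometric mean, natural
logarithm throughout (the choice of base only rescales balances; a fixed
convention makes numeric results reproducible), and `y = x / p` the
relative masses shifted by per-edge weights `p`. With `p = (1, ..., 1)`
the nu terms are set cardinalities and `gm` is the plain geometric mean.

The weights down-weigh edges with little placement mass, which are noisy:
`p_j` multiplies a central tendency of the absolute masses of edge j
across samples (default: geometric mean with +1 pseudo-counts) with a
norm of its relative masses (default: Euclidean). All-zero edges are
floored at 1e-12 so `x / p` stays finite. Two further numerical choices
are deliberate and exposed: zero masses inside a sample receive a
pseudo-mass of `0.65 *` the sample's smallest nonzero mass before
closure (`pseudo_factor`), and tip edges are excluded from
`per_edge_balances()` by default, mirroring the imbalance convention.
Unweighted balances are insensitive to single high-mass branches (the
geometric mean barely moves), so correlations or k-means on unweighted
balances are discouraged, though not blocked.

## Placement-Factorization

`placement_factorization()` greedily identifies *winning edges* whose
induced bipartition best separates samples according to their meta-data.
Each iteration evaluates every candidate edge (non-tip, not a previous
winner) inside its current subtree: the balance between the two edge sets
the candidate separates (within that subtree only, with the globally
fixed edge weights but nu sums restricted to the subtree) is computed per
sample, and scored by `glm_objective()` — the deviance reduction of a GLM
predicting the balances from all meta-data columns simultaneously
(gaussian family by default, so the objective is TSS - RSS of the linear
fit; categorical features are dummy-coded by the formula interface). The
maximizing edge wins, ties towards the lowest edge number; its subtree is
split and later iterations never contrast across it, which keeps factors
orthogonal and lets nested signals surface. After i iterations the
non-winner edges form i + 1 disjoint subtrees; winning edges are the
boundaries between them. The algorithm runs for a fixed number of
iterations; a data-driven stopping rule is not implemented. Edges whose
model cannot be fit (fewer complete cases than parameters, or an empty
side) are skipped.

`factor_ordination()` turns the winning-edge balances into a
samples-by-factors table (optionally scaled to [-1, 1] preserving the
zero point), and `objective_map()` renders each iteration's objective
values on the tree, with tip edges, previous winners and skipped edges in
neutral gray.

## Visualization

`edge_dispersion()` (sd, variance, or the variance-mean ratio, which
makes low-mass edges visible but is undefined at zero mean) and
`edge_correlation()` (Pearson or Spearman with average ranks, pairwise
deletion of missing values, constant columns marked undefined) map
per-edge summaries back onto the tree. Sample statistics (n-1) are used
throughout. `edge_pca()` is a PCA of the column-centered imbalance
matrix (standardization optional). `render_tree()` writes a CSV of edge
number/value/color, a Newick string with per-edge color comments, and
optionally an SVG; correlations and balances use a divergent palette
fixed at 0, dispersions a sequential one, and log scaling
(`log10(v + eps)`, eps = smallest positive value / 10) affects rendering
only, never stored values.

## The synthetic generator

`random_tree()` draws unrooted binary trees (2·taxa − 3 edges, preorder
edge numbers) with exponential branch lengths of mean 0.1, a typical
scale for reference phylogenies. `simulate_samples()` emulates the
structure of placed metabarcoding samples: each query spreads unit LWR
over 1–3 adjacent edges with Dirichlet weights and uniform positions,
mimicking placement uncertainty among neighboring branches; planted
clades receive controlled fractions of each sample's queries; numeric
meta-data features are linear in the realized clade mass fraction plus
gaussian noise (sd 0.1 by default — small against fractions spanning
[0, 0.8], as in a study with a strong environmental driver), and group
labels give categorical features. Everything is a deterministic function
of one seed (Mersenne-Twister, no global state). Defaults (10 samples,
100 queries) are deliberately desk-scale; the planted-partition tests use
20 + 20 samples of 60 queries on 16-taxon trees, and factorization
recovery uses 20 samples of 60 queries on 14-taxon trees.

What the generator does *not* emulate: real reference trees are orders of
magnitude larger; real LWR profiles are driven by sequence similarity and
can be heavy-tailed across distant clades; multiplicities follow
abundance distributions far more skewed than 1 + Poisson(1); and
meta-data relationships in nature are rarely linear with homoscedastic
noise. Passing tests therefore demonstrate correctness of the
algorithms and recoverability of planted signals under controlled
conditions — not statistical power on any particular empirical dataset.

## Known limitations

* Branch-length-based edge weighting for balances is not implemented.
* Factorization has no statistical stopping criterion; choose the number
  of iterations from the objective decay.
* The KR distance is the order-1 distance only.
* Pairwise distance computation is serial; the `threads` argument is
  accepted for interface stability and does not change results.
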