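# placemass

Scalable post-analysis of **phylogenetic placement** data in R.

Phylogenetic placement maps anonymous query sequences (reads, amplicons,
OTUs) from environmental samples onto the branches of a fixed reference
tree, assigning each candidate branch a *likelihood weight ratio* (LWR)
that sums to 1 per query. `placemass` reads the standard jplace format
and treats those LWRs as point masses on the edges of the tree. On top of
this mass interpretation it provides, for sets of samples placed on the
same reference tree:

* **Edge masses and imbalances** — per-edge mass vectors `c`, unit-mass
  normalization (relative abundances `x`), branch binning, squashing
  (weighted averaging of mass distributions), and the edge imbalance
  (root-side minus non-root-side mass, ignoring the edge itself), plus
  the n × m sample-by-edge matrices built from them.
* **KR distance** — the order-1 phylogenetic Kantorovich–Rubinstein
  (earth mover) distance between unit-mass samples with the tree-path
  ground metric, computed exactly in one postorder pass.
* **Clustering** — Squash Clustering (agglomerative, merging clusters by
  averaging their mass distributions), Phylogenetic k-means (Lloyd with
  KR distances and squash centroids), Imbalance k-means (Euclidean Lloyd
  on imbalance vectors), and elbow diagnostics.
* **Visualization** — Edge Dispersion, Edge Correlation against
  meta-data features, Edge PCA on the imbalance matrix, and color-mapped
  trees (CSV / Newick-with-colors / SVG).
* **Balances** — a placement adaptation of the phylogenetic isometric
  log-ratio transform: for disjoint edge sets R, S,
  `y* = sqrt(nu_R nu_S / (nu_R + nu_S)) · log( gm(y_R, p_R) / gm(y_S, p_S) )`,
  with mass-based edge weights `p_j = (prod_i (c_ji + 1))^(1/n) · ||x_j||_2`
  down-weighing low-mass edges.
* **Placement-Factorization** — greedy identification of *winning edges*
  maximizing a GLM deviance objective `omega = null deviance − residual
  deviance` of balances regressed on meta-data; iterative splitting into
  orthogonal subtrees, balance ordinations, and objective-value tree
  maps.
* **Synthetic data** — a fully seeded generator for random reference
  trees, placement samples with planted clade signals, and meta-data with
  controlled correlation to clade masses, so every method is testable
  without external data.

## Worked example

```r
library(placemass)

tree <- random_tree(16, seed = 1)                 # 29-edge reference tree
fix <- simulate_samples(
  tree, n_samples = 12, n_queries = 100,
  planted = list(list(edge_num = 11, fraction = c(0.05, 0.7), noise_sd = 0.05)),
  seed = 1
)
fix$samples[[1]]
#> place_sample 'sample_001': 100 pqueries, 196 placements, total mass 100

# which clades track the meta-data feature?
imb <- placement_matrix(fix$samples, "imbalances")
ec  <- edge_correlation(imb, fix$metadata$feature_11, method = "spearman")
head(sort(abs(ec), decreasing = TRUE), 4)
#>        11         7        13         1
#> 0.9720280 0.9230769 0.8881119 0.8671329

# pairwise KR distances
d <- pairwise_kr(fix$samples)
round(d[1:4, 1:4], 4)
#>            sample_001 sample_002 sample_003 sample_004
#> sample_001     0.0000     0.0564     0.1328     0.2726
#> sample_002     0.0564     0.0000     0.1128     0.2494
#> sample_003     0.1328     0.1128     0.0000     0.1520
#> sample_004     0.2726     0.2494     0.1520     0.0000

# factorization: which edge best explains the meta-data?
pf <- placement_factorization(fix$samples, fix$metadata, iterations = 2)
pf
#> place_factorization: 2 factor(s) on 12 samples (gaussian family, weighted)
#>   factor 1: edge 11, objective 59.9343, |R|=24 |S|=4
#>   factor 2: edge 13, objective 1.54981, |R|=1 |S|=2
```

The fixture plants a mass gradient on the clade behind edge 11 and makes
the meta-data feature linear in that clade's mass. Edge Correlation puts
its strongest coefficient (0.972) on exactly that edge, the KR matrix
separates high-fraction from low-fraction samples, and
Placement-Factorization selects edge 11 as the first winning edge with an
objective two orders of magnitude above the runner-up iteration.

A command-line wrapper with the same functionality is installed at
`inst/cli/placemass` (subcommands `simulate`, `dispersion`, `correlate`,
`edge-pca`, `krd-matrix`, `squash`, `kmeans-phylo`, `kmeans-imbalance`,
`balances`, `factorize`).

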