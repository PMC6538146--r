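test_that("squash clustering of two samples joins them at half their distance", {
  tree <- random_tree(8, seed = 4)
  fix <- simulate_samples(tree, n_samples = 2, n_queries = 30, seed = 4)
  d <- kr_distance(mass_points(fix$samples[[1]]), mass_points(fix$samples[[2]]))
  sq <- squash_clustering(fix$samples)
  expect_equal(nrow(sq$merges), 1L)
  expect_equal(sq$merges$distance, d)
  expect_equal(sort(sq$tree$tip.label), sort(sample_names(fix$samples)))
  expect_equal(unname(sq$tree$edge.length), rep(d / 2, 2))
})

test_that("the closest pair merges first, duplicates form a zero cherry", {
  tree <- random_tree(10, seed = 9)
  fix <- simulate_samples(tree, n_samples = 3, n_queries = 40, seed = 9)
  # duplicate sample 2 under a new name
  dup <- fix$samples[[2]]
  dup$name <- "dup"
  samples <- c(fix$samples, list(dup))
  mps <- lapply(samples, mass_points)
  # exhaustive pair enumeration oracle for the first merge
  n <- length(mps)
  dmat <- matrix(Inf, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) dmat[i, j] <- kr_distance(mps[[i]], mps[[j]])
  first <- arrayInd(which.min(dmat), dim(dmat))
  sq <- squash_clustering(samples)
  expect_equal(sort(unname(unlist(sq$merges[1, c("left", "right")]))),
               sort(as.vector(first)))
  # duplicated samples are joined by a zero-length cherry
  expect_equal(sq$merges$distance[1], 0)
  cherry_edges <- sq$tree$edge.length[
    sq$tree$edge[, 2] %in% match(c(samples[[2]]$name, "dup"), sq$tree$tip.label)
  ]
  expect_equal(unname(cherry_edges), c(0, 0))
  expect_error(squash_clustering(fix$samples[1]), "at least two")
})

test_that("squash clustering centroids are normalized mass distributions", {
  tree <- random_tree(9, seed = 15)
  fix <- simulate_samples(tree, n_samples = 5, n_queries = 30, seed = 15)
  sq <- squash_clustering(fix$samples)
  expect_equal(placemass:::points_total(sq$centroids[[1]]), 1, tolerance = 1e-9)
  f <- tempfile(fileext = ".nwk")
  write_squash_tree(sq, f)
  re <- ape::read.tree(f)
  expect_equal(sort(re$tip.label), sort(sample_names(fix$samples)))
})

test_that("both k-means variants recover a planted two-group structure", {
  fix <- planted_partition_fixture(n_per_group = 10, taxa = 12, seed = 101,
                                   n_queries = 40)
  for (seed in 1:3) {
    km <- phylogenetic_kmeans(fix$samples, 2, seed = seed, bins = 2)
    expect_equal(adjusted_rand(km$assignment, fix$group), 1.0)
    km2 <- imbalance_kmeans(
      placement_matrix(fix$samples, "imbalances"), 2, seed = seed
    )
    expect_equal(adjusted_rand(km2$assignment, fix$group), 1.0)
  }
})

test_that("k-means edge cases: k = n, k = 1, and invalid k", {
  tree <- random_tree(8, seed = 23)
  fix <- simulate_samples(tree, n_samples = 5, n_queries = 25, seed = 23)
  kn <- phylogenetic_kmeans(fix$samples, 5, seed = 1)
  expect_equal(kn$variance, 0, tolerance = 1e-12)
  expect_equal(sort(unique(kn$assignment)), 1:5)
  k1 <- phylogenetic_kmeans(fix$samples, 1, seed = 1)
  # the single centroid is the equal-weight squash of all samples
  ref <- squash(fix$samples, renormalize = TRUE)
  expect_equal(as_mass_vector(k1$centroids[[1]]), as_mass_vector(ref),
               tolerance = 1e-12)
  expect_error(phylogenetic_kmeans(fix$samples, 0, seed = 1), "at least 1")
  expect_error(phylogenetic_kmeans(fix$samples, 6, seed = 1), "exceed")
  mat <- placement_matrix(fix$samples, "imbalances")
  expect_equal(imbalance_kmeans(mat, 5, seed = 1)$variance, 0, tolerance = 1e-12)
  expect_error(imbalance_kmeans(mat, 9, seed = 1), "exceed")
})

test_that("identical samples exercise the empty-cluster repair and terminate", {
  tree <- small_tree()
  X <- matrix(1, 6, 3, dimnames = list(paste0("s", 1:6), c("2", "3", "4")))
  km <- imbalance_kmeans(X, 2, seed = 1)
  expect_equal(sort(unique(km$assignment)), 1:2)
  expect_true(km$iterations <= 100)
})

test_that("the Lloyd objective never increases across iterations", {
  fix <- planted_partition_fixture(n_per_group = 8, taxa = 10, seed = 5,
                                   n_queries = 30)
  mat <- placement_matrix(fix$samples, "imbalances")
  for (seed in 1:5) {
    km <- imbalance_kmeans(mat, 3, seed = seed, init = "random")
    expect_true(all(diff(km$objective_history) <= 1e-12))
  }
  km_p <- phylogenetic_kmeans(fix$samples, 3, seed = 2, bins = 2)
  expect_true(all(diff(km_p$objective_history) <= 1e-12))
})

test_that("a converged Euclidean k-means is a fixed point of stats::kmeans", {
  fix <- planted_partition_fixture(n_per_group = 8, taxa = 10, seed = 33,
                                   n_queries = 30)
  X <- placement_matrix(fix$samples, "imbalances")
  km <- imbalance_kmeans(X, 2, seed = 7)
  # centroid property: each centroid is the mean of its members
  for (cl in 1:2) {
    expect_equal(km$centroids[[cl]],
                 colMeans(X[km$assignment == cl, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # handing the centroids to the reference implementation changes nothing
  centers <- do.call(rbind, km$centroids)
  ref <- suppressWarnings(
    stats::kmeans(X, centers = centers, algorithm = "Lloyd", iter.max = 1)
  )
  expect_equal(unname(ref$cluster), km$assignment)
  expect_equal(ref$tot.withinss / nrow(X), km$variance, tolerance = 1e-9)
})

test_that("two bins per edge do not alter planted cluster assignments", {
  fix <- planted_partition_fixture(n_per_group = 8, taxa = 12, seed = 71,
                                   n_queries = 40)
  km_exact <- phylogenetic_kmeans(fix$samples, 2, seed = 3)
  km_b2 <- phylogenetic_kmeans(fix$samples, 2, seed = 3, bins = 2)
  expect_equal(adjusted_rand(km_exact$assignment, km_b2$assignment), 1.0)
})

test_that("fixed seeds give identical clusterings", {
  fix <- planted_partition_fixture(n_per_group = 6, taxa = 10, seed = 11,
                                   n_queries = 25)
  a <- phylogenetic_kmeans(fix$samples, 2, seed = 42, bins = 1)
  b <- phylogenetic_kmeans(fix$samples, 2, seed = 42, bins = 1)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$variance, b$variance)
  mat <- placement_matrix(fix$samples, "imbalances")
  expect_identical(imbalance_kmeans(mat, 2, seed = 9)$assignment,
                   imbalance_kmeans(mat, 2, seed = 9)$assignment)
})

test_that("the elbow curve drops to zero at k = n and kinks at the truth", {
  tree <- random_tree(20, seed = 55)
  picks <- disjoint_clades(tree, 3)
  group <- rep(1:3, each = 6)
  fix <- simulate_samples(
    tree, n_samples = 18, n_queries = 40,
    planted = lapply(1:3, function(g) {
      list(edge_num = tree$edge_num[picks[g]],
           fraction = ifelse(group == g, 0.85, 0.02), feature = FALSE)
    }),
    seed = 55
  )
  mat <- placement_matrix(fix$samples, "imbalances")
  curve <- elbow_curve(mat, k_range = c(1:6, 18), variant = "imbalance",
                       seed = 1, restarts = 5)
  expect_equal(curve$variance[curve$k == 18], 0, tolerance = 1e-12)
  expect_true(all(diff(curve$variance) <= 1e-9))
  # elbow: largest second difference of the variance curve at k = 3
  v <- curve$variance[curve$k %in% 1:6]
  second_diff <- v[1:4] - 2 * v[2:5] + v[3:6]
  expect_equal(which.max(second_diff) + 1L, 3L)
})
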