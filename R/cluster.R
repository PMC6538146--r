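#' Squash Clustering
#'
#' Agglomerative hierarchical clustering of placement samples: repeatedly
#' merge the pair of clusters with the smallest KR distance, where a merged
#' cluster is represented by the weighted average (squash) of its members'
#' mass distributions, weighted by member counts. Unlike purely
#' distance-based linkage methods, every cluster remains a mass distribution
#' on the reference tree and distances are always true KR distances between
#' those distributions.
#'
#' The branch length from a merged node to each child is half the KR
#' distance between the two merged clusters, so tips correspond to samples
#' and path lengths reflect KR distances between clusters. Ties in the pair
#' selection are broken by lexicographic cluster index for determinism.
#'
#' @param samples list of two or more [place_sample] or `mass_points`
#'   objects on a shared tree; normalized to unit mass internally.
#' @param bins optional branch binning to speed up KR computations.
#' @return object of class `squash_tree`: a list with `tree` (an
#'   [ape::phylo] of the clustering), `merges` (per-merge data.frame) and
#'   `centroids` (the squashed `mass_points` per internal node).
#' @export
squash_clustering <- function(samples, bins = NULL) {
  n <- length(samples)
  if (n < 2) stop("need at least two samples to cluster")
  mps <- lapply(samples, function(s) {
    if (is.null(bins)) mass_points(s, normalize = TRUE)
    else bin_masses(s, b = bins, normalize = TRUE)
  })
  check_shared_tree(mps)
  labels <- vapply(mps, function(x) x$name, character(1))
  # active clusters: mass distribution, member count, node id in merge tree
  clusters <- lapply(seq_len(n), function(i) {
    list(mp = mps[[i]], size = 1L, node = i)
  })
  next_node <- n + 1L
  edges <- list()
  heights <- numeric(0)
  merges <- list()
  dist_cache <- matrix(NA_real_, n, n)
  pair_dist <- function(i, j) kr_distance(clusters[[i]]$mp, clusters[[j]]$mp)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) dist_cache[i, j] <- pair_dist(i, j)
  }
  step <- 0L
  while (length(clusters) > 1) {
    step <- step + 1L
    nn <- length(clusters)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(nn - 1)) {
      for (j in (i + 1):nn) {
        dij <- dist_cache[i, j]
        if (dij < best_d) {
          best_d <- dij
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    ci <- clusters[[i]]; cj <- clusters[[j]]
    merged <- squash(
      list(ci$mp, cj$mp), weights = c(ci$size, cj$size),
      renormalize = TRUE, normalize = FALSE
    )
    merged$name <- sprintf("cluster_%d", step)
    node <- next_node
    next_node <- next_node + 1L
    edges[[length(edges) + 1L]] <- c(node, ci$node, best_d / 2)
    edges[[length(edges) + 1L]] <- c(node, cj$node, best_d / 2)
    merges[[step]] <- data.frame(
      step = step, left = ci$node, right = cj$node,
      distance = best_d, size = ci$size + cj$size
    )
    new_cluster <- list(mp = merged, size = ci$size + cj$size, node = node)
    keep <- setdiff(seq_len(nn), c(i, j))
    new_cache <- matrix(NA_real_, nn - 1, nn - 1)
    if (length(keep)) {
      new_cache[seq_along(keep), seq_along(keep)] <-
        dist_cache[keep, keep, drop = FALSE]
    }
    clusters <- c(clusters[keep], list(new_cluster))
    for (k in seq_along(keep)) {
      dk <- kr_distance(clusters[[k]]$mp, merged)
      new_cache[k, nn - 1] <- dk
    }
    dist_cache <- new_cache
  }
  # assemble an ape phylo from the recorded edges
  em <- do.call(rbind, edges)
  n_internal <- next_node - n - 1L
  # renumber: tips 1..n keep ids; internal nodes must be n+1..n+n_internal
  # with the root first; our last created node is the root
  old_internal <- (n + 1L):(next_node - 1L)
  new_id <- c(seq_len(n), rev(seq_along(old_internal)) + n)
  phylo <- list(
    edge = cbind(new_id[em[, 1]], new_id[em[, 2]]),
    edge.length = em[, 3],
    tip.label = labels,
    Nnode = n_internal
  )
  class(phylo) <- "phylo"
  phylo <- ape::reorder.phylo(phylo, "cladewise")
  centroids <- lapply(clusters, function(cl) cl$mp)
  structure(
    list(tree = phylo, merges = do.call(rbind, merges), centroids = centroids),
    class = "squash_tree"
  )
}

#' @export
print.squash_tree <- function(x, ...) {
  cat(sprintf(
    "squash_tree: %d samples, %d merges (max KR distance %.6g)\n",
    length(x$tree$tip.label), nrow(x$merges), max(x$merges$distance)
  ))
  invisible(x)
}

#' Write a squash clustering tree to Newick
#' @param x a `squash_tree`.
#' @param path output file.
#' @export
write_squash_tree <- function(x, path) {
  ape::write.tree(x$tree, file = path)
  invisible(path)
}

# ---- k-means ---------------------------------------------------------------

# k-means++ seeding: given a function dist_to(center_idx) returning the
# distances of all items to one item, pick k item indices
kmeanspp_init <- function(n, k, dist_fun) {
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- dist_fun(centers[1])^2
    for (i in 2:k) {
      if (all(d2 == 0)) {
        centers[i] <- sample.int(n, 1)
      } else {
        centers[i] <- sample.int(n, 1, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, dist_fun(centers[i])^2)
    }
  }
  centers
}

# shared Lloyd iteration for both k-means flavours.
#  assign_fun(centroids) -> list(assign = int vector, dist = numeric vector)
#  update_fun(assign)    -> list of k centroids
#  variance_of(cluster assignment distances) = mean squared distance
lloyd_kmeans <- function(n, k, init_centroids, assign_fun, update_fun,
                         max_iter = 100L) {
  centroids <- init_centroids
  assign_prev <- rep(0L, n)
  iter <- 0L
  objective <- numeric(0)
  repeat {
    iter <- iter + 1L
    asg <- assign_fun(centroids)
    assignment <- asg$assign
    dists <- asg$dist
    objective <- c(objective, mean(dists^2))
    # empty-cluster repair: move the sample furthest from its centroid in
    # the highest-variance cluster into each empty cluster
    empty <- setdiff(seq_len(k), unique(assignment))
    for (e in empty) {
      sizes <- tabulate(assignment, nbins = k)
      vars <- vapply(seq_len(k), function(cl) {
        if (sizes[cl] < 2) return(-Inf)
        mean(dists[assignment == cl]^2)
      }, numeric(1))
      donor <- which.max(vars)
      members <- which(assignment == donor)
      far <- members[order(-dists[members], members)][1]
      assignment[far] <- e
      dists[far] <- 0
    }
    if (identical(assignment, assign_prev) || iter >= max_iter) {
      centroids <- update_fun(assignment)
      asg2 <- assign_fun(centroids)
      variance <- mean(asg2$dist^2)
      return(list(
        assignment = assignment, centroids = centroids,
        iterations = iter, variance = variance,
        objective_history = c(objective, variance),
        converged = iter < max_iter
      ))
    }
    assign_prev <- assignment
    centroids <- update_fun(assignment)
  }
}

#' Phylogenetic k-means clustering
#'
#' Lloyd-style k-means on placement samples where the distance between a
#' sample and a centroid is the KR distance and the centroid update is the
#' average mass distribution (squash) of the cluster members. Initialized
#' with k-means++ seeding (selection probability proportional to the
#' squared KR distance to the nearest already selected sample), or uniform
#' random sample selection with `init = "random"`.
#'
#' @param samples list of [place_sample] or `mass_points` objects on a
#'   shared tree; normalized internally.
#' @param k number of clusters (1..n).
#' @param seed RNG seed for the initialization; fixed seed gives an
#'   identical clustering.
#' @param max_iter iteration cap of the Lloyd loop.
#' @param bins optional branch binning applied to samples and centroids.
#' @param init `"kmeans++"` (default) or `"random"`.
#' @return object of class `place_kmeans`: assignments, centroid
#'   `mass_points`, iteration count and the mean squared KR distance of
#'   samples to their centroids (`variance`).
#' @export
phylogenetic_kmeans <- function(samples, k, seed = 1L, max_iter = 100L,
                                bins = NULL, init = c("kmeans++", "random")) {
  init <- match.arg(init)
  n <- length(samples)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k must not exceed the number of samples")
  mps <- lapply(samples, function(s) {
    if (is.null(bins)) mass_points(s, normalize = TRUE)
    else bin_masses(s, b = bins, normalize = TRUE)
  })
  check_shared_tree(mps)
  dist_to_item <- function(i) {
    vapply(mps, function(x) kr_distance(x, mps[[i]]), numeric(1))
  }
  centers0 <- with_seed(seed, {
    if (init == "kmeans++") kmeanspp_init(n, k, dist_to_item)
    else sample.int(n, k)
  })
  assign_fun <- function(centroids) {
    dmat <- vapply(centroids, function(cen) {
      vapply(mps, function(x) kr_distance(x, cen), numeric(1))
    }, numeric(n))
    assign <- max.col(-dmat, ties.method = "first")
    list(assign = assign, dist = dmat[cbind(seq_len(n), assign)])
  }
  update_fun <- function(assignment) {
    lapply(seq_len(k), function(cl) {
      members <- which(assignment == cl)
      squash(mps[members], renormalize = TRUE, normalize = FALSE)
    })
  }
  res <- lloyd_kmeans(
    n, k, lapply(centers0, function(i) mps[[i]]),
    assign_fun, update_fun, max_iter = max_iter
  )
  structure(
    c(res, list(
      k = k, variant = "phylogenetic", seed = seed,
      sample_names = vapply(mps, function(x) x$name, character(1))
    )),
    class = "place_kmeans"
  )
}

#' Imbalance k-means clustering
#'
#' Standard Euclidean k-means (Lloyd's algorithm) on the rows of the edge
#' imbalance matrix of normalized samples. Imbalances implicitly capture
#' the tree topology, so no tree traversals are needed, making this variant
#' much faster than [phylogenetic_kmeans()].
#'
#' @param imbalance_matrix n x m matrix of per-sample edge imbalances (see
#'   [placement_matrix()] with `content = "imbalances"`).
#' @param k number of clusters.
#' @param seed RNG seed for initialization.
#' @param max_iter iteration cap.
#' @param init `"kmeans++"` or `"random"`.
#' @return a `place_kmeans` object; centroids are imbalance vectors.
#' @export
imbalance_kmeans <- function(imbalance_matrix, k, seed = 1L, max_iter = 100L,
                             init = c("kmeans++", "random")) {
  init <- match.arg(init)
  X <- as.matrix(imbalance_matrix)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k must not exceed the number of samples")
  dist_to_item <- function(i) {
    sqrt(colSums((t(X) - X[i, ])^2))
  }
  centers0 <- with_seed(seed, {
    if (init == "kmeans++") kmeanspp_init(n, k, dist_to_item)
    else sample.int(n, k)
  })
  assign_fun <- function(centroids) {
    dmat <- vapply(centroids, function(cen) {
      sqrt(colSums((t(X) - cen)^2))
    }, numeric(n))
    assign <- max.col(-dmat, ties.method = "first")
    list(assign = assign, dist = dmat[cbind(seq_len(n), assign)])
  }
  update_fun <- function(assignment) {
    lapply(seq_len(k), function(cl) {
      colMeans(X[assignment == cl, , drop = FALSE])
    })
  }
  res <- lloyd_kmeans(
    n, k, lapply(seq_len(k), function(i) X[centers0[i], ]),
    assign_fun, update_fun, max_iter = max_iter
  )
  structure(
    c(res, list(
      k = k, variant = "imbalance", seed = seed,
      sample_names = rownames(X)
    )),
    class = "place_kmeans"
  )
}

#' @export
print.place_kmeans <- function(x, ...) {
  cat(sprintf(
    "%s k-means: k=%d, %d samples, %d iterations, variance %.6g\n",
    x$variant, x$k, length(x$assignment), x$iterations, x$variance
  ))
  invisible(x)
}

#' Elbow curve for choosing k
#'
#' Runs a k-means variant over a range of k values and reports the average
#' squared distance of samples to their assigned centroids, the quantity
#' whose "elbow" suggests the number of natural clusters.
#'
#' @param x list of samples (phylogenetic variant) or an imbalance matrix
#'   (imbalance variant).
#' @param k_range integer vector of k values.
#' @param variant `"imbalance"` or `"phylogenetic"`.
#' @param seed RNG seed; run r for k uses seed + r - 1.
#' @param restarts independent restarts per k; the smallest variance wins.
#' @param ... passed to the k-means function.
#' @return data.frame with columns `k` and `variance`.
#' @export
elbow_curve <- function(x, k_range, variant = c("imbalance", "phylogenetic"),
                        seed = 1L, restarts = 1L, ...) {
  variant <- match.arg(variant)
  fit <- function(k, s) {
    if (variant == "imbalance") imbalance_kmeans(x, k, seed = s, ...)
    else phylogenetic_kmeans(x, k, seed = s, ...)
  }
  out <- lapply(k_range, function(k) {
    vars <- vapply(seq_len(restarts), function(r) {
      fit(k, seed + r - 1L)$variance
    }, numeric(1))
    data.frame(k = k, variance = min(vars))
  })
  do.call(rbind, out)
}
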