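#' Random edge-numbered reference tree
#'
#' Generates a random unrooted, strictly bifurcating reference tree (its
#' top-level trifurcation serves as root) with exponentially distributed
#' branch lengths and jplace edge numbers assigned in preorder. Fully
#' deterministic per seed.
#'
#' @param taxa number of tips (>= 3).
#' @param seed RNG seed.
#' @param mean_branch_length mean of the exponential branch lengths.
#' @return a [place_tree] with `2 * taxa - 3` edges.
#' @export
random_tree <- function(taxa, seed = 1L, mean_branch_length = 0.1) {
  taxa <- as.integer(taxa)
  if (taxa < 3L) stop("need at least 3 taxa")
  phylo <- with_seed(seed, {
    ape::rtree(taxa, rooted = FALSE,
               br = function(n) stats::rexp(n, rate = 1 / mean_branch_length))
  })
  phylo <- ape::reorder.phylo(phylo, "cladewise")
  place_tree(phylo, seq_len(nrow(phylo$edge)) - 1L)
}

# edge rows of a planted clade: the defining edge plus everything below it
planted_rows <- function(tree, edge_num) {
  i <- edge_row(tree, edge_num)
  c(i, clade_rows(tree, i))
}

#' Simulate placement samples with planted clade signals
#'
#' Generates `n_samples` placement samples on a reference tree. Each query
#' sequence spreads its unit LWR over one to three edges of a chosen
#' region (Dirichlet-distributed weights, uniform positions along the
#' edges), emulating placement uncertainty. Optionally, "planted" clades
#' receive a controlled fraction of each sample's queries, and per-sample
#' numeric meta-data features are generated as a linear function of the
#' realized clade mass fraction plus gaussian noise - the ground truth
#' against which correlation, clustering and factorization methods are
#' checked.
#'
#' Nested planted clades are allowed; a query assigned to an outer clade
#' is placed on the outer clade's edges excluding any nested planted clade.
#'
#' @param tree a [place_tree], e.g. from [random_tree()].
#' @param n_samples number of samples.
#' @param n_queries query sequences per sample.
#' @param planted list of planted clades; each a list with `edge_num` (the
#'   clade-defining edge), `fraction` (expected fraction of queries placed
#'   in the clade: a scalar, a length-2 range sampled uniformly per
#'   sample, or a length-`n_samples` vector), and optionally `feature`
#'   (generate a numeric meta-data column, default `TRUE`), `alpha`
#'   (linear coefficient, default 1) and `noise_sd` (gaussian noise of the
#'   feature, default 0.1).
#' @param group optional character/factor vector of per-sample group
#'   labels, added as a categorical meta-data column.
#' @param multiplicity `"unit"` (all 1) or `"mixed"` (1 + Poisson(1)).
#' @param mass_loss fraction of LWR discarded per query (emulates filtered
#'   unlikely placements; 0 keeps every LWR sum at exactly 1).
#' @param seed RNG seed; the whole fixture is a deterministic function of
#'   it.
#' @param write_dir if given, writes one jplace file per sample plus
#'   `metadata.csv` into this directory.
#' @return list with `samples` (list of [place_sample]), `metadata`
#'   (data.frame with rownames = sample names), `fractions` (realized
#'   per-clade mass fractions, samples x clades), and `tree`.
#' @export
simulate_samples <- function(tree, n_samples = 10L, n_queries = 100L,
                             planted = list(), group = NULL,
                             multiplicity = c("unit", "mixed"),
                             mass_loss = 0, seed = 1L, write_dir = NULL) {
  stopifnot(inherits(tree, "place_tree"))
  multiplicity <- match.arg(multiplicity)
  m <- n_edges(tree)
  bl <- tree$phylo$edge.length
  n_clades <- length(planted)
  clade_all <- lapply(planted, function(pl) planted_rows(tree, pl$edge_num))
  # region of a clade: its rows minus any nested planted clade's rows
  regions <- lapply(seq_along(clade_all), function(k) {
    rows <- clade_all[[k]]
    for (j in seq_along(clade_all)) {
      if (j != k && all(clade_all[[j]] %in% rows)) {
        rows <- setdiff(rows, clade_all[[j]])
      }
    }
    rows
  })
  background <- setdiff(seq_len(m), unlist(clade_all))
  if (!length(background)) stop("planted clades cover the whole tree")
  if (!is.null(group) && length(group) != n_samples) {
    stop("one group label per sample required")
  }
  # per-sample target fractions, one column per planted clade
  frac_of <- function(pl) {
    fr <- pl$fraction
    if (length(fr) == 1) rep(fr, n_samples)
    else if (length(fr) == 2) stats::runif(n_samples, fr[1], fr[2])
    else if (length(fr) == n_samples) as.numeric(fr)
    else stop("fraction must be a scalar, a range, or one value per sample")
  }
  adjacency <- lapply(seq_len(m), function(i) {
    node_p <- tree$phylo$edge[i, 1]
    node_c <- tree$phylo$edge[i, 2]
    setdiff(which(tree$phylo$edge[, 1] %in% c(node_p, node_c) |
                    tree$phylo$edge[, 2] == node_p), i)
  })
  res <- with_seed(seed, {
    target <- if (n_clades) {
      do.call(cbind, lapply(planted, frac_of))
    } else {
      matrix(0, n_samples, 0)
    }
    if (any(target < 0) || any(rowSums(target) > 1)) {
      stop("planted fractions must be in [0,1] and sum to at most 1 per sample")
    }
    samples <- vector("list", n_samples)
    realized <- matrix(0, n_samples, n_clades)
    for (s in seq_len(n_samples)) {
      probs <- c(target[s, ], 1 - sum(target[s, ]))
      region_of_query <- sample.int(n_clades + 1L, n_queries, replace = TRUE,
                                    prob = probs)
      mult <- if (multiplicity == "unit") {
        rep(1, n_queries)
      } else {
        1 + stats::rpois(n_queries, 1)
      }
      plc <- vector("list", n_queries)
      for (q in seq_len(n_queries)) {
        reg <- if (region_of_query[q] <= n_clades) {
          regions[[region_of_query[q]]]
        } else {
          background
        }
        center <- reg[sample.int(length(reg), 1)]
        nbr <- intersect(adjacency[[center]], reg)
        n_extra <- min(sample.int(3L, 1) - 1L, length(nbr))
        edges_q <- c(center, if (n_extra) nbr[sample.int(length(nbr), n_extra)])
        w <- stats::rgamma(length(edges_q), 1)
        lwr <- w / sum(w) * (1 - mass_loss)
        plc[[q]] <- data.frame(
          query = q,
          edge_num = tree$edge_num[edges_q],
          like_weight_ratio = lwr,
          proximal_length = stats::runif(length(edges_q)) * bl[edges_q],
          pendant_length = 0
        )
      }
      smp <- place_sample(
        sprintf("sample_%03d", s), tree,
        query_names = as.list(sprintf("s%03d_q%04d", s, seq_len(n_queries))),
        multiplicity = mult,
        placements = do.call(rbind, plc)
      )
      masses <- edge_masses(smp)
      for (k in seq_len(n_clades)) {
        realized[s, k] <- sum(masses[clade_all[[k]]]) / sum(masses)
      }
      samples[[s]] <- smp
    }
    # meta-data: numeric feature per feature-bearing clade, then group
    meta <- data.frame(row.names = sprintf("sample_%03d", seq_len(n_samples)))
    for (k in seq_len(n_clades)) {
      pl <- planted[[k]]
      if (isFALSE(pl$feature)) next
      alpha <- if (is.null(pl$alpha)) 1 else pl$alpha
      noise_sd <- if (is.null(pl$noise_sd)) 0.1 else pl$noise_sd
      meta[[sprintf("feature_%d", pl$edge_num)]] <-
        alpha * realized[, k] + stats::rnorm(n_samples, 0, noise_sd)
    }
    if (!is.null(group)) meta$group <- factor(group)
    list(samples = samples, metadata = meta, fractions = realized)
  })
  res$tree <- tree
  if (n_clades) {
    colnames(res$fractions) <- vapply(planted, function(pl) {
      sprintf("clade_%d", pl$edge_num)
    }, character(1))
  }
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (smp in res$samples) {
      write_jplace(smp, file.path(write_dir, paste0(smp$name, ".jplace")))
    }
    meta_out <- cbind(sample = rownames(res$metadata), res$metadata)
    write_csv_det(meta_out, file.path(write_dir, "metadata.csv"))
  }
  res
}
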