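#' Phylogenetic Kantorovich-Rubinstein distance between two samples
#'
#' The order-1 KR (earth mover) distance between two unit-mass placement
#' distributions on the same reference tree, with the tree-path metric as
#' ground distance: the minimal total mass movement (mass times displacement
#' along tree paths) needed to turn one distribution into the other.
#'
#' Computed in a single postorder pass: the signed net mass difference
#' (a - b) is accumulated towards the root, and every infinitesimal tree
#' segment contributes `|net mass crossing it| * segment length`; within an
#' edge, segments run between consecutive mass points.
#'
#' @param a,b [place_sample] or `mass_points` objects on the same tree with
#'   equal total mass (within `1e-6`); typically normalized to unit mass.
#' @param renormalize rescale both inputs to unit mass instead of erroring
#'   on unequal totals (a warning is still emitted).
#' @return non-negative distance; zero iff the distributions coincide.
#' @export
kr_distance <- function(a, b, renormalize = FALSE) {
  a <- mass_points(a, normalize = FALSE)
  b <- mass_points(b, normalize = FALSE)
  tree <- check_shared_tree(list(a, b))
  ta <- points_total(a)
  tb <- points_total(b)
  if (abs(ta - tb) > 1e-6 * max(ta, tb, 1)) {
    if (renormalize) {
      warning("unequal total masses; renormalizing both samples to unit mass")
    } else {
      stop("samples must have equal total mass for the KR distance ",
           "(use normalized samples or renormalize = TRUE)")
    }
  }
  if (renormalize) {
    a <- normalize_points(a)
    b <- normalize_points(b)
  }
  phylo <- tree$phylo
  len <- phylo$edge.length
  m <- n_edges(tree)
  nnode <- length(phylo$tip.label) + phylo$Nnode
  net <- numeric(nnode)
  d <- 0
  # reverse preorder visits every edge after all edges below it
  for (i in rev(seq_len(m))) {
    child <- phylo$edge[i, 2]
    L <- len[i]
    p <- c(a$pos[[i]], b$pos[[i]])
    w <- c(a$mass[[i]], -b$mass[[i]])
    if (length(p)) {
      ord <- order(p, decreasing = TRUE)
      p <- p[ord]
      w <- w[ord]
      cums <- cumsum(c(net[child], w))
      widths <- c(L, p) - c(p, 0)
      d <- d + sum(abs(cums) * widths)
      net[phylo$edge[i, 1]] <- net[phylo$edge[i, 1]] + cums[length(cums)]
    } else {
      d <- d + abs(net[child]) * L
      net[phylo$edge[i, 1]] <- net[phylo$edge[i, 1]] + net[child]
    }
  }
  d
}

#' Pairwise KR distance matrix for a set of samples
#'
#' @param samples list of [place_sample] or `mass_points` objects on a
#'   shared tree; each is normalized to unit mass before comparison.
#' @param bins optional number of bins per edge; branch binning speeds up
#'   large analyses with negligible loss of accuracy.
#' @param threads reserved for API compatibility; the result is independent
#'   of its value.
#' @return symmetric n x n matrix of KR distances with zero diagonal and
#'   sample names as dimnames.
#' @export
pairwise_kr <- function(samples, bins = NULL, threads = 1L) {
  n <- length(samples)
  if (n < 2) stop("need at least two samples")
  mps <- lapply(samples, function(s) {
    if (is.null(bins)) mass_points(s, normalize = TRUE)
    else bin_masses(s, b = bins, normalize = TRUE)
  })
  check_shared_tree(mps)
  nms <- vapply(mps, function(x) x$name, character(1))
  d <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- kr_distance(mps[[i]], mps[[j]])
    }
  }
  d
}
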