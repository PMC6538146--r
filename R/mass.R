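#' Per-edge placement masses of a sample
#'
#' Accumulates the mass of every placement (`multiplicity * LWR`) onto its
#' edge. The total equals the sum of pquery multiplicities for fully placed
#' pqueries.
#'
#' @param sample a [place_sample].
#' @return named numeric vector of length `m` in canonical (preorder) edge
#'   order, names = edge numbers; attribute `normalized` is `FALSE`.
#' @export
edge_masses <- function(sample) {
  tree <- sample$tree
  m <- n_edges(tree)
  c_vec <- numeric(m)
  pl <- sample$placements
  if (nrow(pl) > 0) {
    rows <- edge_row(tree, pl$edge_num)
    mass <- sample$multiplicity[pl$query] * pl$like_weight_ratio
    agg <- tapply(mass, rows, sum)
    c_vec[as.integer(names(agg))] <- agg
  }
  names(c_vec) <- tree$edge_num
  attr(c_vec, "normalized") <- FALSE
  c_vec
}

#' Normalize a per-edge mass vector to unit total mass
#'
#' Divides each entry by the total, converting absolute into relative
#' abundances (the closure of the composition). Idempotent.
#'
#' @param x numeric per-edge mass vector with non-negative entries.
#' @return vector summing to 1, with attribute `normalized = TRUE`.
#' @export
normalize_masses <- function(x) {
  tot <- sum(x)
  if (!is.finite(tot) || tot <= 0) stop("cannot normalize an all-zero mass vector")
  out <- x / tot
  attr(out, "normalized") <- TRUE
  out
}

#' Placement mass points on the reference tree
#'
#' Materializes the placements of a sample as point masses at their proximal
#' positions on the edges, the representation used by the KR distance,
#' binning and squashing. Pendant lengths are ignored: mass lives on the
#' reference tree edges only.
#'
#' @param sample a [place_sample], or an existing `mass_points` object
#'   (returned unchanged apart from optional normalization).
#' @param normalize scale the total mass to 1.
#' @return object of class `mass_points` with per-edge position and mass
#'   lists (sorted by position), in canonical edge order.
#' @export
mass_points <- function(sample, normalize = TRUE) {
  if (inherits(sample, "mass_points")) {
    return(if (normalize) normalize_points(sample) else sample)
  }
  stopifnot(inherits(sample, "place_sample"))
  tree <- sample$tree
  m <- n_edges(tree)
  pos <- vector("list", m)
  mass <- vector("list", m)
  for (i in seq_len(m)) {
    pos[[i]] <- numeric(0)
    mass[[i]] <- numeric(0)
  }
  pl <- sample$placements
  if (nrow(pl) > 0) {
    rows <- edge_row(tree, pl$edge_num)
    w <- sample$multiplicity[pl$query] * pl$like_weight_ratio
    for (grp in split(seq_len(nrow(pl)), rows)) {
      i <- rows[grp[1]]
      p <- pl$proximal_length[grp]
      ord <- order(p)
      # aggregate identical positions
      agg <- tapply(w[grp][ord], p[ord], sum)
      pos[[i]] <- as.numeric(names(agg))
      mass[[i]] <- as.numeric(agg)
    }
  }
  out <- structure(
    list(
      tree = tree, pos = pos, mass = mass,
      binned = FALSE, b = NA_integer_, name = sample$name
    ),
    class = "mass_points"
  )
  if (normalize) normalize_points(out) else out
}

normalize_points <- function(mp) {
  tot <- sum(unlist(mp$mass))
  if (tot <= 0) stop("cannot normalize mass points with zero total mass")
  mp$mass <- lapply(mp$mass, function(v) v / tot)
  mp
}

points_total <- function(mp) sum(unlist(mp$mass))

#' @export
print.mass_points <- function(x, ...) {
  cat(sprintf(
    "mass_points%s: %d edges, %d points, total mass %.6g\n",
    if (x$binned) sprintf(" (binned, b=%d)", x$b) else "",
    n_edges(x$tree), length(unlist(x$pos)), points_total(x)
  ))
  invisible(x)
}

#' Collapse mass points to a per-edge mass vector
#' @param mp a `mass_points` object.
#' @return named numeric per-edge vector in canonical order.
#' @export
as_mass_vector <- function(mp) {
  stopifnot(inherits(mp, "mass_points"))
  out <- vapply(mp$mass, sum, numeric(1))
  names(out) <- mp$tree$edge_num
  attr(out, "normalized") <- isTRUE(abs(sum(out) - 1) < 1e-9)
  out
}

#' Branch binning of placement masses
#'
#' Divides every edge into `b` equally sized intervals and accumulates each
#' mass point into the bin whose center is nearest to its position; ties at
#' exact midpoints go to the lower-index bin. Bin centers lie at
#' `(j - 0.5) * branch_length / b`. With `b = 1` this reduces each edge to a
#' single point carrying the edge mass. Per-edge and total masses are
#' conserved.
#'
#' @param sample a [place_sample] or `mass_points` object.
#' @param b number of bins per edge (>= 1).
#' @param normalize scale total mass to 1.
#' @return a binned `mass_points` object.
#' @export
bin_masses <- function(sample, b = 1L, normalize = TRUE) {
  b <- as.integer(b)
  if (is.na(b) || b < 1L) stop("number of bins `b` must be >= 1")
  mp <- mass_points(sample, normalize = normalize)
  tree <- mp$tree
  len <- tree$phylo$edge.length
  for (i in seq_along(mp$pos)) {
    p <- mp$pos[[i]]
    if (!length(p)) next
    L <- len[i]
    if (L <= 0) {
      mp$pos[[i]] <- 0
      mp$mass[[i]] <- sum(mp$mass[[i]])
      next
    }
    j <- ceiling(p * b / L)
    j[j < 1L] <- 1L
    j[j > b] <- b
    agg <- tapply(mp$mass[[i]], j, sum)
    jj <- as.integer(names(agg))
    mp$pos[[i]] <- (jj - 0.5) * L / b
    mp$mass[[i]] <- as.numeric(agg)
  }
  mp$binned <- TRUE
  mp$b <- b
  mp
}

#' Squash samples into their weighted average mass distribution
#'
#' Computes the weighted average of the mass distributions of several
#' samples on the same tree, joining the (scaled) placement mass points on
#' corresponding edges. Squashing a cluster of samples summarizes it by one
#' mass distribution on the tree.
#'
#' @param samples list of [place_sample] or `mass_points` objects on the
#'   same tree.
#' @param weights non-negative weights, not all zero; default equal.
#' @param renormalize scale the result to unit total mass (only meaningful
#'   when the inputs are normalized).
#' @param normalize normalize each input before averaging.
#' @return a `mass_points` object.
#' @export
squash <- function(samples, weights = NULL, renormalize = FALSE, normalize = TRUE) {
  if (inherits(samples, c("place_sample", "mass_points"))) samples <- list(samples)
  if (!length(samples)) stop("need at least one sample to squash")
  mps <- lapply(samples, mass_points, normalize = normalize)
  tree <- check_shared_tree(mps)
  if (is.null(weights)) weights <- rep(1, length(mps))
  if (length(weights) != length(mps)) stop("one weight per sample required")
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative and not all zero")
  }
  w <- weights / sum(weights)
  m <- n_edges(tree)
  pos <- vector("list", m)
  mass <- vector("list", m)
  for (i in seq_len(m)) {
    p <- unlist(lapply(mps, function(x) x$pos[[i]]))
    v <- unlist(lapply(seq_along(mps), function(k) mps[[k]]$mass[[i]] * w[k]))
    if (length(p)) {
      agg <- tapply(v, p, sum)
      pos[[i]] <- as.numeric(names(agg))
      mass[[i]] <- as.numeric(agg)
    } else {
      pos[[i]] <- numeric(0)
      mass[[i]] <- numeric(0)
    }
  }
  bs <- vapply(mps, function(x) x$binned, logical(1))
  out <- structure(
    list(
      tree = tree, pos = pos, mass = mass,
      binned = all(bs), b = if (all(bs)) mps[[1]]$b else NA_integer_,
      name = "squash"
    ),
    class = "mass_points"
  )
  if (renormalize) normalize_points(out) else out
}

#' Edge imbalances of a per-edge mass vector
#'
#' For every edge, the sum of masses on the root side of the edge minus the
#' sum on the non-root side, ignoring the mass on the edge itself. Computed
#' in O(m) with two tree passes. On a unit-mass (normalized) sample every
#' imbalance lies in `[-1, 1]`, and the imbalance of a leaf edge is simply
#' the total mass minus the edge's own mass; leaf edges are therefore
#' dropped by default.
#'
#' @param x per-edge mass vector in canonical order (see [edge_masses()]).
#' @param tree the [place_tree] the vector lives on.
#' @param include_tips keep leaf-edge entries.
#' @return named numeric vector of imbalances (inner edges only unless
#'   `include_tips`).
#' @export
edge_imbalances <- function(x, tree, include_tips = FALSE) {
  stopifnot(inherits(tree, "place_tree"))
  m <- n_edges(tree)
  if (length(x) != m) stop("mass vector length does not match the tree")
  phylo <- tree$phylo
  total <- sum(x)
  # pass 1 (postorder): mass strictly below each edge's child node
  below <- numeric(m)
  # iterate edges in reverse preorder so children are done before parents
  kids_of_node <- split(seq_len(m), phylo$edge[, 1])
  for (i in rev(seq_len(m))) {
    rows <- kids_of_node[[as.character(phylo$edge[i, 2])]]
    if (!is.null(rows)) below[i] <- sum(below[rows] + x[rows])
  }
  # pass 2: root side = total - below - own mass
  imb <- (total - below - as.numeric(x)) - below
  names(imb) <- tree$edge_num
  if (!include_tips) imb <- imb[!tree$tip_edge]
  imb
}

#' Build the n x m placement data matrix of a set of samples
#'
#' Stacks per-sample, per-edge vectors into a matrix with one row per sample
#' and one column per edge (canonical preorder column order), holding either
#' edge masses or edge imbalances, from absolute or normalized (relative)
#' abundances.
#'
#' @param samples list of [place_sample]s on a shared tree.
#' @param content `"masses"` or `"imbalances"`.
#' @param normalize use relative abundances (unit mass per sample).
#' @param include_tips keep leaf-edge columns (imbalances only; mass
#'   matrices always keep all edges).
#' @return numeric matrix with sample names as row names, edge numbers as
#'   column names, and attribute `content`.
#' @export
placement_matrix <- function(samples, content = c("masses", "imbalances"),
                             normalize = TRUE, include_tips = FALSE) {
  content <- match.arg(content)
  tree <- check_shared_tree(samples)
  rows <- lapply(samples, function(s) {
    v <- edge_masses(s)
    if (normalize) v <- normalize_masses(v)
    if (content == "imbalances") {
      v <- edge_imbalances(v, tree, include_tips = include_tips)
    }
    v
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- sample_names(samples)
  attr(mat, "content") <- content
  attr(mat, "normalized") <- normalize
  mat
}
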