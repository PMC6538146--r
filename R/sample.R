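#' Placement sample
#'
#' A `place_sample` holds the placements of all query sequences (pqueries) of
#' one environmental sample on a shared reference tree. Each pquery carries
#' one or more placements, i.e. candidate positions on edges of the tree,
#' each with a likelihood weight ratio (LWR). Interpreted as mass, a fully
#' placed pquery contributes `multiplicity * 1.0` to the tree in total.
#'
#' Placements are stored flat for efficiency: one row per placement, with a
#' `query` index into the per-pquery vectors.
#'
#' @param name sample name.
#' @param tree a [place_tree].
#' @param query_names list of character vectors, one per pquery.
#' @param multiplicity numeric vector of pquery multiplicities (> 0).
#' @param placements data.frame with columns `query`, `edge_num`,
#'   `like_weight_ratio`, `proximal_length`, `pendant_length`.
#'
#' @return object of class `place_sample`.
#' @export
place_sample <- function(name, tree, query_names, multiplicity, placements) {
  stopifnot(inherits(tree, "place_tree"))
  nq <- length(query_names)
  multiplicity <- as.numeric(multiplicity)
  if (length(multiplicity) != nq) stop("one multiplicity per pquery required")
  if (any(!is.finite(multiplicity)) || any(multiplicity <= 0)) {
    stop("multiplicities must be positive")
  }
  req <- c("query", "edge_num", "like_weight_ratio", "proximal_length", "pendant_length")
  if (!all(req %in% names(placements))) {
    stop("placements must have columns: ", paste(req, collapse = ", "))
  }
  placements <- placements[, req]
  if (nq > 0 && !setequal(unique(placements$query), seq_len(nq))) {
    stop("every pquery needs at least one placement")
  }
  lwr <- placements$like_weight_ratio
  if (any(lwr < 0) || any(lwr > 1 + 1e-6)) {
    stop("like_weight_ratio values must lie in [0, 1]")
  }
  sums <- vapply(split(lwr, placements$query), sum, numeric(1))
  if (any(sums > 1 + 1e-6)) {
    stop("LWR sum of a pquery exceeds 1")
  }
  rows <- edge_row(tree, placements$edge_num) # errors on unknown edges
  bl <- tree$phylo$edge.length[rows]
  prox <- placements$proximal_length
  if (any(prox < 0) || any(prox > bl)) {
    warning("proximal_length outside [0, branch_length]; clamping")
    placements$proximal_length <- pmin(pmax(prox, 0), bl)
  }
  structure(
    list(
      name = name,
      tree = tree,
      query_names = query_names,
      multiplicity = multiplicity,
      placements = placements
    ),
    class = "place_sample"
  )
}

#' @export
print.place_sample <- function(x, ...) {
  cat(sprintf(
    "place_sample '%s': %d pqueries, %d placements, total mass %.6g\n",
    x$name, n_queries(x), nrow(x$placements), total_mass(x)
  ))
  invisible(x)
}

#' Number of pqueries in a sample
#' @param sample a `place_sample`
#' @export
n_queries <- function(sample) {
  length(sample$query_names)
}

#' Total placement mass of a sample
#'
#' Sum over pqueries of `multiplicity * sum(LWR)`. For fully placed pqueries
#' this equals the sum of multiplicities (the number of query sequences when
#' all multiplicities are 1).
#'
#' @param sample a `place_sample`
#' @export
total_mass <- function(sample) {
  if (nrow(sample$placements) == 0) return(0)
  sum(sample$multiplicity[sample$placements$query] *
        sample$placements$like_weight_ratio)
}

# shared-tree check used by all multi-sample operations
check_shared_tree <- function(samples) {
  trees <- lapply(samples, function(s) s$tree)
  ref <- trees[[1]]
  for (t in trees[-1]) {
    if (!identical(t$edge_num, ref$edge_num) ||
        !identical(t$phylo$edge, ref$phylo$edge)) {
      stop("all samples must be placed on the same reference tree")
    }
  }
  ref
}

sample_names <- function(samples) {
  vapply(samples, function(s) s$name, character(1))
}
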