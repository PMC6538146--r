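#' @importFrom ape read.tree reorder.phylo
NULL

#' Reference tree with jplace edge numbering
#'
#' A `place_tree` wraps an [ape::phylo] object together with the integer edge
#' numbers used by the jplace format to address branches. Edges are kept in
#' cladewise (preorder) order, which is the canonical column order of all
#' per-edge vectors and matrices produced by this package.
#'
#' @param phylo an [ape::phylo] tree with branch lengths; strictly
#'   bifurcating except for an optional top-level trifurcation at the root
#'   (the usual representation of an unrooted binary tree).
#' @param edge_num integer vector of jplace edge numbers, one per row of
#'   `phylo$edge` (in the edge order of `phylo`).
#'
#' @return an object of class `place_tree` with elements `phylo`,
#'   `edge_num` (cladewise order), `span` (number of descendant edges per
#'   edge), and `tip_edge` (logical).
#' @export
place_tree <- function(phylo, edge_num) {
  if (!inherits(phylo, "phylo")) stop("`phylo` must be an ape phylo object")
  if (is.null(phylo$edge.length)) stop("reference tree must have branch lengths")
  m <- nrow(phylo$edge)
  edge_num <- as.integer(edge_num)
  if (length(edge_num) != m) stop("`edge_num` must have one entry per edge")
  if (anyDuplicated(edge_num)) stop("edge numbers must be unique")
  if (any(!is.finite(phylo$edge.length)) || any(phylo$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  # reorder cladewise, carrying the edge numbers along
  ord <- attr(phylo, "order")
  if (is.null(ord) || ord != "cladewise") {
    key <- paste(phylo$edge[, 1], phylo$edge[, 2])
    phylo2 <- ape::reorder.phylo(phylo, "cladewise")
    edge_num <- edge_num[match(paste(phylo2$edge[, 1], phylo2$edge[, 2]), key)]
    phylo <- phylo2
  }
  ntip <- length(phylo$tip.label)
  root <- ntip + 1L
  nchild <- tabulate(phylo$edge[, 1], nbins = ntip + phylo$Nnode)
  inner <- setdiff(unique(phylo$edge[, 1]), root)
  if (any(nchild[inner] != 2L)) {
    stop("reference tree must be strictly bifurcating (top-level trifurcation allowed)")
  }
  if (!nchild[root] %in% c(2L, 3L)) {
    stop("root must have two children, or three for an unrooted tree")
  }
  tree <- structure(
    list(
      phylo = phylo,
      edge_num = edge_num,
      span = edge_spans(phylo),
      tip_edge = phylo$edge[, 2] <= ntip
    ),
    class = "place_tree"
  )
  tree
}

# number of strict descendant edges per edge row; relies on cladewise
# (preorder) edge order: descendants of row i occupy rows (i+1)..(i+span[i])
edge_spans <- function(phylo) {
  m <- nrow(phylo$edge)
  span <- integer(m)
  # children rows grouped by parent node
  for (i in rev(seq_len(m))) {
    child <- phylo$edge[i, 2]
    rows <- which(phylo$edge[, 1] == child)
    span[i] <- sum(span[rows]) + length(rows)
  }
  span
}

#' @export
print.place_tree <- function(x, ...) {
  cat(sprintf(
    "place_tree: %d tips, %d edges (edge numbers %d..%d)\n",
    length(x$phylo$tip.label), n_edges(x), min(x$edge_num), max(x$edge_num)
  ))
  invisible(x)
}

#' Number of edges of a reference tree
#' @param tree a `place_tree`
#' @return integer edge count `m`
#' @export
n_edges <- function(tree) {
  stopifnot(inherits(tree, "place_tree"))
  length(tree$edge_num)
}

#' Edge numbers in canonical (preorder) column order
#' @param tree a `place_tree`
#' @export
edge_numbers <- function(tree) {
  stopifnot(inherits(tree, "place_tree"))
  tree$edge_num
}

# row index (canonical order) for given edge numbers; errors on unknown ids
edge_row <- function(tree, edge_num) {
  idx <- match(as.integer(edge_num), tree$edge_num)
  if (anyNA(idx)) {
    stop(sprintf(
      "edge number(s) %s not present in reference tree",
      paste(edge_num[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}

# rows of all strict descendant edges of edge row i (contiguous by preorder)
clade_rows <- function(tree, i) {
  s <- tree$span[i]
  if (s == 0L) integer(0) else (i + 1L):(i + s)
}

#' Bipartition of the edge set induced by one edge
#'
#' Removing edge `e` splits the remaining edges into the set on the root side
#' of `e` and the set on the non-root (distal) side, i.e. the clade below `e`.
#'
#' @param tree a `place_tree`
#' @param edge_num a single jplace edge number
#' @return list with integer vectors `root_side` and `distal_side` of edge
#'   numbers; together with `e` itself they cover all edges.
#' @export
edge_partition <- function(tree, edge_num) {
  i <- edge_row(tree, edge_num)
  distal <- clade_rows(tree, i)
  list(
    root_side = tree$edge_num[setdiff(seq_len(n_edges(tree)), c(i, distal))],
    distal_side = tree$edge_num[distal]
  )
}

#' Branch lengths in canonical edge order
#' @param tree a `place_tree`
#' @export
branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "place_tree"))
  stats::setNames(tree$phylo$edge.length, tree$edge_num)
}

# ---- jplace Newick dialect -------------------------------------------------

# Parse a Newick string whose edges are annotated with jplace edge numbers,
# either "{N}" (pplacer style) or "[N]" (EPA style); the dialect is decided
# by the first match. Returns a place_tree.
parse_jplace_tree <- function(newick) {
  s <- trimws(newick)
  curly <- regexpr("\\{\\d+\\}", s)
  square <- regexpr("\\[\\d+\\]", s)
  if (curly < 0 && square < 0) stop("tree string carries no jplace edge numbers")
  if (curly < 0 || (square > 0 && square < curly)) {
    s <- gsub("\\[(\\d+)\\]", "{\\1}", s)
  }
  # move "{N}" into the node label (tag "@#N@") so ape can read the tree
  s <- gsub("(:[0-9]*\\.?[0-9]*(?:[eE][+-]?[0-9]+)?)\\{(\\d+)\\}", "@#\\2@\\1", s)
  s <- gsub("\\{(\\d+)\\}", "@#\\1@", s) # edge numbers without branch length
  phylo <- ape::read.tree(text = s)
  if (is.null(phylo)) stop("malformed Newick string in jplace tree")
  get_tag <- function(labels) {
    tag <- rep(NA_integer_, length(labels))
    hit <- regmatches(labels, regexpr("@#\\d+@", labels))
    has <- grepl("@#\\d+@", labels)
    tag[has] <- as.integer(gsub("[@#]", "", hit))
    tag
  }
  tip_tag <- get_tag(phylo$tip.label)
  node_tag <- if (is.null(phylo$node.label)) {
    rep(NA_integer_, phylo$Nnode)
  } else {
    get_tag(phylo$node.label)
  }
  phylo$tip.label <- sub("@#\\d+@", "", phylo$tip.label)
  if (!is.null(phylo$node.label)) {
    phylo$node.label <- sub("@#\\d+@", "", phylo$node.label)
  }
  ntip <- length(phylo$tip.label)
  child <- phylo$edge[, 2]
  edge_num <- rep(NA_integer_, length(child))
  is_tip <- child <= ntip
  edge_num[is_tip] <- tip_tag[child[is_tip]]
  edge_num[!is_tip] <- node_tag[child[!is_tip] - ntip]
  if (anyNA(edge_num)) stop("jplace tree: some edges lack an edge number")
  # a root edge number (annotated on the root node itself) has no edge; drop
  phylo$root.edge <- NULL
  place_tree(phylo, edge_num)
}

# shortest decimal representation that round-trips to the same double
fmt_shortest <- function(x) {
  vapply(x, function(v) {
    if (v == floor(v) && abs(v) < 2^31) {
      return(sprintf("%d", as.integer(v)))
    }
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

# Newick string with "{N}" edge number annotations after each branch length
write_jplace_tree <- function(tree) {
  phylo <- tree$phylo
  ntip <- length(phylo$tip.label)
  children <- split(seq_len(nrow(phylo$edge)), phylo$edge[, 1])
  rec <- function(node, edge_i) {
    lab <- if (node <= ntip) phylo$tip.label[node] else ""
    rows <- children[[as.character(node)]]
    inner <- if (is.null(rows)) lab else {
      paste0("(", paste(vapply(rows, function(r) {
        rec(phylo$edge[r, 2], r)
      }, character(1)), collapse = ","), ")", lab)
    }
    if (is.na(edge_i)) {
      inner
    } else {
      paste0(
        inner, ":", fmt_shortest(phylo$edge.length[edge_i]),
        "{", tree$edge_num[edge_i], "}"
      )
    }
  }
  paste0(rec(ntip + 1L, NA), ";")
}
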