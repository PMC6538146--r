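#' Edge weights for the placement ILR transform
#'
#' Balances can down-weigh edges with little placement mass, which are
#' noisier and less reliable. The weight of edge `j` multiplicatively
#' combines a central tendency of the absolute edge masses across samples
#' with a norm of the relative edge masses across samples. The default is
#' the geometric mean with +1 pseudo-counts (avoiding skew from edges
#' without any mass) times the Euclidean norm:
#' `p_j = (prod_i (c_ji + 1))^(1/n) * sqrt(sum_i x_ji^2)`.
#'
#' All-zero edges would receive weight 0; these are floored at a tiny
#' positive value so that the shifted composition `x / p` stays finite.
#'
#' @param abs_matrix n x m matrix of absolute edge masses (samples x edges).
#' @param rel_matrix n x m matrix of relative (normalized) edge masses.
#' @param tendency `"geometric"` (default), `"arithmetic"` or `"median"`.
#' @param norm `"euclidean"` (default), `"manhattan"`, `"maximum"` or
#'   `"aitchison"`.
#' @param floor smallest admissible weight.
#' @return numeric vector of m positive edge weights named by edge number,
#'   with the configuration attached as attributes.
#' @export
compute_edge_weights <- function(abs_matrix, rel_matrix,
                                 tendency = c("geometric", "arithmetic", "median"),
                                 norm = c("euclidean", "manhattan", "maximum", "aitchison"),
                                 floor = 1e-12) {
  tendency <- match.arg(tendency)
  norm <- match.arg(norm)
  Ca <- as.matrix(abs_matrix)
  Cr <- as.matrix(rel_matrix)
  if (!all(dim(Ca) == dim(Cr))) stop("matrices must have identical dimensions")
  cent <- switch(tendency,
    geometric = exp(colMeans(log(Ca + 1))),
    arithmetic = colMeans(Ca),
    median = apply(Ca, 2, stats::median)
  )
  nrm <- switch(norm,
    euclidean = sqrt(colSums(Cr^2)),
    manhattan = colSums(abs(Cr)),
    maximum = apply(abs(Cr), 2, max),
    aitchison = apply(Cr, 2, function(col) {
      pos <- col[col > 0]
      if (length(pos) < 2) return(0)
      lc <- log(pos)
      sqrt(sum((lc - mean(lc))^2))
    })
  )
  p <- pmax(cent * nrm, floor)
  names(p) <- colnames(Ca)
  attr(p, "tendency") <- tendency
  attr(p, "norm") <- norm
  p
}

#' Weighted geometric mean
#'
#' `gm(y, p) = exp( sum(p * log y) / sum(p) )`; with unit weights this is
#' the ordinary geometric mean.
#'
#' @param y positive values.
#' @param p positive weights (default unit weights).
#' @export
weighted_geometric_mean <- function(y, p = rep(1, length(y))) {
  if (!length(y)) stop("empty input")
  if (any(y <= 0)) stop("geometric mean requires strictly positive values")
  if (any(p <= 0)) stop("weights must be strictly positive")
  exp(sum(p * log(y)) / sum(p))
}

#' Balance between two disjoint edge sets
#'
#' The ILR coordinate contrasting the (weighted) geometric mean masses of
#' two disjoint edge sets R and S:
#' `y* = sqrt(nu_R * nu_S / (nu_R + nu_S)) * log( gm(y_R, p_R) / gm(y_S, p_S) )`
#' with `nu_R = sum(p_R)`, `nu_S = sum(p_S)` (the set sizes under unit
#' weights) and the natural logarithm. Interchanging R and S flips the
#' sign. The scaling term ensures unit length of the ILR basis elements.
#'
#' @param R,S disjoint, non-empty vectors of edge numbers.
#' @param y named vector of shifted relative masses (`x / p`) per edge.
#' @param p named vector of edge weights (see [compute_edge_weights()]);
#'   default unit weights over `names(y)`.
#' @return the balance value, with `nu_R`/`nu_S` as attributes.
#' @export
balance <- function(R, S, y, p = NULL) {
  if (!length(R) || !length(S)) stop("R and S must be non-empty")
  R <- as.character(R)
  S <- as.character(S)
  if (length(intersect(R, S))) stop("R and S must be disjoint")
  if (is.null(p)) p <- stats::setNames(rep(1, length(y)), names(y))
  if (anyNA(match(c(R, S), names(y)))) stop("edge sets refer to unknown edges")
  nu_r <- sum(p[R])
  nu_s <- sum(p[S])
  val <- sqrt(nu_r * nu_s / (nu_r + nu_s)) *
    log(weighted_geometric_mean(y[R], p[R]) / weighted_geometric_mean(y[S], p[S]))
  attr(val, "nu_R") <- nu_r
  attr(val, "nu_S") <- nu_s
  val
}

# per-sample shifted composition y = x / p with pseudo-mass handling:
# zero masses receive eps = pseudo_factor * smallest nonzero mass before
# closure, so log-ratios stay finite. Returns an n x m matrix.
shifted_compositions <- function(mass_matrix_abs, p, pseudo_factor = 0.65) {
  X <- as.matrix(mass_matrix_abs)
  t(apply(X, 1, function(c_vec) {
    nz <- c_vec[c_vec > 0]
    if (!length(nz)) stop("sample without any placement mass")
    eps <- pseudo_factor * min(nz)
    c_vec[c_vec == 0] <- eps
    x <- c_vec / sum(c_vec)
    x / p
  }))
}

#' Per-edge balances for a set of samples
#'
#' For every inner (non-tip) edge, the balance between the edges on the
#' root side (R) and the edges on the non-root side (S) of that edge,
#' computed per sample. The resulting n x m' matrix is the balance
#' counterpart of the imbalance matrix: imbalances contrast the two sides
#' by a difference of sums, balances by a log-ratio of geometric means.
#'
#' Zero masses are handled by a per-sample pseudo-mass (a configurable
#' fraction of the smallest nonzero mass) added before closure.
#'
#' @param samples list of [place_sample]s on a shared tree.
#' @param edge_weights per-edge weights from [compute_edge_weights()], or
#'   `NULL` for unweighted balances (p = 1).
#' @param include_tips also compute balances for tip edges (whose S set is
#'   empty and which are therefore skipped; present for interface symmetry
#'   with [placement_matrix()]).
#' @param pseudo_factor pseudo-mass fraction for zero handling.
#' @return matrix with samples as rows and inner edges as columns
#'   (`content = "balances"`).
#' @export
per_edge_balances <- function(samples, edge_weights = NULL,
                              include_tips = FALSE, pseudo_factor = 0.65) {
  tree <- check_shared_tree(samples)
  abs_mat <- placement_matrix(samples, "masses", normalize = FALSE)
  p <- if (is.null(edge_weights)) {
    stats::setNames(rep(1, n_edges(tree)), tree$edge_num)
  } else {
    edge_weights
  }
  Y <- shifted_compositions(abs_mat, p, pseudo_factor)
  colnames(Y) <- tree$edge_num
  inner <- which(!tree$tip_edge)
  out <- matrix(
    NA_real_, nrow(Y), length(inner),
    dimnames = list(rownames(abs_mat), tree$edge_num[inner])
  )
  all_rows <- seq_len(n_edges(tree))
  for (k in seq_along(inner)) {
    i <- inner[k]
    S_rows <- clade_rows(tree, i)
    R_rows <- setdiff(all_rows, c(i, S_rows))
    R <- as.character(tree$edge_num[R_rows])
    S <- as.character(tree$edge_num[S_rows])
    for (s in seq_len(nrow(Y))) {
      out[s, k] <- as.numeric(balance(R, S, Y[s, ], p))
    }
  }
  attr(out, "content") <- "balances"
  attr(out, "edge_weights") <- p
  out
}

#' Write a balance matrix and its edge weights to CSV
#'
#' The balance matrix is written keyed by sample, the edge weight vector
#' keyed by edge number, and the configuration is echoed into a JSON
#' sidecar for reproducibility.
#'
#' @param balances matrix from [per_edge_balances()].
#' @param out_prefix path prefix for `<prefix>_balances.csv`,
#'   `<prefix>_edge_weights.csv` and `<prefix>_config.json`.
#' @return written file paths, invisibly.
#' @export
write_balances <- function(balances, out_prefix) {
  bal_df <- data.frame(sample = rownames(balances), balances,
                       check.names = FALSE)
  f1 <- paste0(out_prefix, "_balances.csv")
  write_csv_det(bal_df, f1)
  p <- attr(balances, "edge_weights")
  f2 <- paste0(out_prefix, "_edge_weights.csv")
  write_csv_det(data.frame(edge_num = names(p), weight = as.numeric(p)), f2)
  f3 <- paste0(out_prefix, "_config.json")
  cfg <- list(
    tendency = attr(p, "tendency"), norm = attr(p, "norm"),
    n_samples = nrow(balances), n_edges = length(p)
  )
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null"), f3)
  invisible(c(f1, f2, f3))
}
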