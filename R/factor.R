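#' GLM deviance objective for factorization
#'
#' Quantifies how well the per-sample meta-data predicts the per-sample
#' contrasts (balances) at a candidate edge: a generalized linear model
#' `contrasts ~ all meta-data columns` is fit and the objective is the
#' reduction in deviance over the null (intercept-only) model,
#' `omega = null_deviance - residual_deviance >= 0`. For the gaussian
#' family this equals the total minus the residual sum of squares of the
#' linear fit. Categorical features are dummy-coded automatically;
#' collinear columns are dropped by the fitter.
#'
#' @param contrasts numeric vector, one contrast (balance) per sample.
#' @param Z data.frame of meta-data features, rows aligned with
#'   `contrasts`.
#' @param family a [stats::family] object; default `gaussian()`.
#' @return the deviance reduction, or `NA` when fewer complete cases than
#'   model parameters plus one are available (the edge is then skipped).
#' @export
glm_objective <- function(contrasts, Z, family = stats::gaussian()) {
  Z <- as.data.frame(Z)
  if (length(contrasts) != nrow(Z)) stop("one contrast per sample required")
  dat <- cbind(data.frame(.response = contrasts), Z)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_par <- tryCatch(
    ncol(stats::model.matrix(.response ~ ., data = dat)),
    error = function(e) Inf
  )
  if (nrow(dat) < n_par + 1) return(NA_real_)
  fit <- stats::glm(.response ~ ., data = dat, family = family)
  max(fit$null.deviance - fit$deviance, 0)
}

#' Placement-Factorization
#'
#' Greedy phylofactorization of placement data: in each iteration, every
#' candidate edge (non-tip, not a previous winner) is evaluated by
#' aggregating the masses of the two edge sets it separates *within its
#' current subtree* into balances (one per sample) and scoring them with
#' the GLM deviance objective against the meta-data. The edge maximizing
#' the objective wins and splits its subtree in two; later iterations never
#' contrast across previous winning edges, which keeps the factors
#' orthogonal and allows nested signals to surface. After `i` iterations
#' the non-winner edges fall into `i + 1` disjoint subtrees.
#'
#' Edge weights for the balances are computed once on the full data set
#' and held fixed; within a subtree, the balance uses only the weights of
#' that subtree's edges. Ties in the objective are broken towards the
#' lowest edge number.
#'
#' @param samples list of [place_sample]s on a shared tree.
#' @param metadata data.frame of per-sample features (rows in sample
#'   order, e.g. from [read_metadata()]).
#' @param iterations number of factors to compute.
#' @param taxon_weights use mass-based edge weights (see
#'   [compute_edge_weights()]); `FALSE` for unweighted balances.
#' @param family GLM family for the objective.
#' @param pseudo_factor pseudo-mass fraction for zero handling in the
#'   shifted compositions.
#' @return object of class `place_factorization`: list of `factors` (each
#'   with winning edge, edge sets, per-edge objective values, per-sample
#'   contrasts and the fitted-model summary), the final `components`
#'   labelling of edges, `tree`, and the settings used.
#' @export
placement_factorization <- function(samples, metadata, iterations = 1L,
                                    taxon_weights = TRUE,
                                    family = stats::gaussian(),
                                    pseudo_factor = 0.65) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  tree <- check_shared_tree(samples)
  metadata <- as.data.frame(metadata)
  if (nrow(metadata) != length(samples)) {
    stop("meta-data must have one row per sample")
  }
  m <- n_edges(tree)
  abs_mat <- placement_matrix(samples, "masses", normalize = FALSE)
  rel_mat <- placement_matrix(samples, "masses", normalize = TRUE)
  p <- if (taxon_weights) {
    compute_edge_weights(abs_mat, rel_mat)
  } else {
    stats::setNames(rep(1, m), tree$edge_num)
  }
  Y <- shifted_compositions(abs_mat, p, pseudo_factor)
  LY <- log(Y) # n x m
  comp <- rep(1L, m) # subtree membership per edge row; 0 marks winners
  next_comp <- 2L
  factors <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    cand <- which(!tree$tip_edge & comp > 0L)
    omega <- rep(NA_real_, m)
    contrasts_by_edge <- vector("list", m)
    for (e in cand) {
      G <- which(comp == comp[e])
      S_rows <- intersect(clade_rows(tree, e), G)
      R_rows <- setdiff(G, c(e, S_rows))
      if (!length(S_rows) || !length(R_rows)) next
      nu_r <- sum(p[R_rows])
      nu_s <- sum(p[S_rows])
      gm_r <- as.vector(LY[, R_rows, drop = FALSE] %*% p[R_rows]) / nu_r
      gm_s <- as.vector(LY[, S_rows, drop = FALSE] %*% p[S_rows]) / nu_s
      ctr <- sqrt(nu_r * nu_s / (nu_r + nu_s)) * (gm_r - gm_s)
      omega[e] <- glm_objective(ctr, metadata, family = family)
      contrasts_by_edge[[e]] <- ctr
    }
    if (all(is.na(omega))) {
      warning("no candidate edges remain; stopping after ", it - 1L, " factors")
      factors <- factors[seq_len(it - 1L)]
      break
    }
    best <- max(omega, na.rm = TRUE)
    winner <- which(omega == best) # ties: lowest edge number
    winner <- winner[which.min(tree$edge_num[winner])]
    G <- which(comp == comp[winner])
    S_rows <- intersect(clade_rows(tree, winner), G)
    R_rows <- setdiff(G, c(winner, S_rows))
    ctr <- contrasts_by_edge[[winner]]
    dat <- cbind(data.frame(.response = ctr), metadata)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    fit <- stats::glm(.response ~ ., data = dat, family = family)
    names(omega) <- tree$edge_num
    factors[[it]] <- list(
      iteration = it,
      edge_num = tree$edge_num[winner],
      R = tree$edge_num[R_rows],
      S = tree$edge_num[S_rows],
      objective = omega,
      contrasts = stats::setNames(ctr, rownames(abs_mat)),
      model = list(
        deviance = fit$deviance,
        null_deviance = fit$null.deviance,
        coefficients = stats::coef(fit)
      )
    )
    comp[S_rows] <- next_comp
    next_comp <- next_comp + 1L
    comp[winner] <- 0L
  }
  structure(
    list(
      factors = factors,
      components = stats::setNames(comp, tree$edge_num),
      tree = tree,
      edge_weights = p,
      taxon_weights = taxon_weights,
      family = family$family,
      sample_names = rownames(abs_mat)
    ),
    class = "place_factorization"
  )
}

#' @export
print.place_factorization <- function(x, ...) {
  cat(sprintf(
    "place_factorization: %d factor(s) on %d samples (%s family, %s)\n",
    length(x$factors), length(x$sample_names), x$family,
    if (x$taxon_weights) "weighted" else "unweighted"
  ))
  for (f in x$factors) {
    cat(sprintf(
      "  factor %d: edge %d, objective %.6g, |R|=%d |S|=%d\n",
      f$iteration, f$edge_num, f$objective[as.character(f$edge_num)],
      length(f$R), length(f$S)
    ))
  }
  invisible(x)
}

#' Balance ordination of a factorization
#'
#' The per-sample balances at each factor's winning edge, usable as a
#' low-dimensional ordination of the samples. Optionally min-max scaled to
#' `[-1, 1]` per factor while preserving the centering at 0 (division by
#' the largest absolute value).
#'
#' @param result a `place_factorization`.
#' @param scale scale each factor column to `[-1, 1]` preserving 0.
#' @return data.frame, samples x factors.
#' @export
factor_ordination <- function(result, scale = FALSE) {
  stopifnot(inherits(result, "place_factorization"))
  if (!length(result$factors)) stop("factorization holds no factors")
  cols <- lapply(result$factors, function(f) {
    v <- f$contrasts
    if (scale) {
      amp <- max(abs(v))
      if (amp > 0) v <- v / amp
    }
    v
  })
  out <- as.data.frame(cols, col.names = sprintf(
    "factor_%d_edge_%d",
    vapply(result$factors, `[[`, integer(1), "iteration"),
    vapply(result$factors, `[[`, integer(1), "edge_num")
  ))
  rownames(out) <- result$sample_names
  out
}

#' Render the objective values of one factorization iteration on the tree
#'
#' Colors every evaluated candidate edge by its objective value; tip
#' edges, previous winners and skipped edges are rendered neutral. The
#' winning edge carries the maximum value.
#'
#' @param result a `place_factorization`.
#' @param iteration which factor's objective map to draw.
#' @param out_prefix,formats passed to [render_tree()].
#' @return written files, invisibly.
#' @export
objective_map <- function(result, iteration, out_prefix,
                          formats = c("csv", "newick")) {
  stopifnot(inherits(result, "place_factorization"))
  if (iteration < 1 || iteration > length(result$factors)) {
    stop("iteration out of range")
  }
  f <- result$factors[[iteration]]
  vals <- edge_values(f$objective, kind = "objective", scale = "linear")
  render_tree(result$tree, vals, out_prefix, palette = "sequential",
              formats = formats)
}
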