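#' Edge Dispersion
#'
#' Per-edge dispersion of a placement data matrix: for every column (edge)
#' of the mass or imbalance matrix, a measure of spread across samples.
#' High-dispersion edges discriminate samples. The index of dispersion
#' (variance-mean ratio) makes differences on low-mass edges visible, at the
#' price of being undefined for zero-mean columns.
#'
#' Sample statistics (n-1 denominator) are used throughout.
#'
#' @param matrix n x m matrix from [placement_matrix()].
#' @param measure `"sd"`, `"variance"` or `"index_of_dispersion"`.
#' @param log_scale store a log10 display scale tag; values themselves are
#'   never transformed (the transform is applied at rendering time only).
#' @return object of class `edge_values`: named numeric vector (edge
#'   numbers), with `NA` marking undefined edges, plus `kind` and `scale`
#'   attributes.
#' @export
edge_dispersion <- function(matrix,
                            measure = c("sd", "variance", "index_of_dispersion"),
                            log_scale = FALSE) {
  measure <- match.arg(measure)
  X <- as.matrix(matrix)
  if (nrow(X) < 2) stop("dispersion needs at least two samples (rows)")
  v <- apply(X, 2, stats::var)
  out <- switch(measure,
    sd = sqrt(v),
    variance = v,
    index_of_dispersion = {
      mu <- colMeans(X)
      res <- v / mu
      res[mu == 0] <- NA_real_
      res
    }
  )
  edge_values(out, kind = paste0("dispersion_", measure),
              scale = if (log_scale) "log" else "linear")
}

#' Edge Correlation
#'
#' Correlation between every edge column of a placement data matrix and one
#' numeric meta-data feature, yielding a per-edge coefficient in [-1, 1]
#' that highlights edges (masses) or clades (imbalances) associated with
#' the feature. Rows with missing feature values are dropped pairwise;
#' constant columns are marked undefined rather than leaking NaN.
#'
#' @param matrix n x m matrix from [placement_matrix()].
#' @param feature numeric vector of length n (one value per sample).
#' @param method `"pearson"` or `"spearman"` (average ranks for ties).
#' @return an `edge_values` vector of correlation coefficients.
#' @export
edge_correlation <- function(matrix, feature,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- as.matrix(matrix)
  feature <- as.numeric(feature)
  if (length(feature) != nrow(X)) stop("one feature value per sample required")
  keep <- !is.na(feature)
  X <- X[keep, , drop = FALSE]
  feature <- feature[keep]
  if (length(feature) < 3) stop("need at least 3 complete pairs")
  vals <- apply(X, 2, function(col) {
    ok <- !is.na(col)
    if (sum(ok) < 3) return(NA_real_)
    if (stats::sd(col[ok]) == 0 || stats::sd(feature[ok]) == 0) return(NA_real_)
    stats::cor(col[ok], feature[ok], method = method)
  })
  edge_values(vals, kind = paste0("correlation_", method), scale = "linear")
}

edge_values <- function(x, kind, scale = "linear") {
  structure(x, kind = kind, scale = scale, class = "edge_values")
}

#' @export
print.edge_values <- function(x, ...) {
  cat(sprintf(
    "edge_values (%s, %s scale): %d edges, %d undefined, range [%.4g, %.4g]\n",
    attr(x, "kind"), attr(x, "scale"), length(x), sum(is.na(x)),
    suppressWarnings(min(x, na.rm = TRUE)), suppressWarnings(max(x, na.rm = TRUE))
  ))
  invisible(x)
}

#' Edge PCA
#'
#' Principal component analysis of the column-centered edge imbalance
#' matrix. Components are mass difference patterns across clades; loadings
#' map back onto edges of the tree, scores place samples in the reduced
#' space. Columns are centered but, by default, not standardized.
#'
#' @param imbalance_matrix n x m imbalance matrix of normalized samples
#'   (tip edges excluded, see [placement_matrix()]).
#' @param components number of components to return.
#' @param standardize scale columns to unit variance before the PCA.
#' @return list with `loadings` (edges x components), `scores` (samples x
#'   components), `sdev`, and `var_explained` (proportion per component).
#' @export
edge_pca <- function(imbalance_matrix, components = 2L, standardize = FALSE) {
  X <- as.matrix(imbalance_matrix)
  components <- as.integer(components)
  maxc <- min(nrow(X) - 1L, ncol(X))
  if (components < 1L || components > maxc) {
    stop("components must be in 1..min(n-1, m) = 1..", maxc)
  }
  if (standardize) {
    keep <- apply(X, 2, stats::sd) > 0
    X <- X[, keep, drop = FALSE]
  }
  p <- stats::prcomp(X, center = TRUE, scale. = standardize)
  idx <- seq_len(components)
  var_all <- p$sdev^2
  list(
    loadings = p$rotation[, idx, drop = FALSE],
    scores = p$x[, idx, drop = FALSE],
    sdev = p$sdev[idx],
    var_explained = var_all[idx] / sum(var_all)
  )
}

#' Map per-edge values to colors
#'
#' Sequential palettes map `[min, max]` linearly; divergent palettes are
#' anchored at a center (0 for correlations and imbalances) with symmetric
#' limits. Undefined values receive the neutral color.
#'
#' @param values numeric vector (e.g. an `edge_values` object).
#' @param palette `"sequential"` or `"divergent"`.
#' @param center anchor for divergent palettes.
#' @param na_color color for undefined entries.
#' @param log_scale render on a log10 scale (`log10(v + eps)` with
#'   `eps` = smallest positive value / 10); sequential palettes only.
#' @return character vector of hex colors.
#' @export
map_colors <- function(values, palette = c("sequential", "divergent"),
                       center = 0, na_color = "#aaaaaa", log_scale = FALSE) {
  palette <- match.arg(palette)
  v <- as.numeric(values)
  out <- rep(na_color, length(v))
  ok <- is.finite(v)
  if (!any(ok)) return(out)
  if (palette == "sequential") {
    if (log_scale) {
      pos <- v[ok & v > 0]
      eps <- if (length(pos)) min(pos) / 10 else 1
      v[ok] <- log10(v[ok] + eps)
    }
    lo <- min(v[ok]); hi <- max(v[ok])
    t <- if (hi > lo) (v[ok] - lo) / (hi - lo) else rep(0.5, sum(ok))
    ramp <- grDevices::colorRamp(c("#ffffcc", "#fd8d3c", "#800026"))
  } else {
    amp <- max(abs(v[ok] - center))
    t <- if (amp > 0) (v[ok] - center) / (2 * amp) + 0.5 else rep(0.5, sum(ok))
    ramp <- grDevices::colorRamp(c("#2166ac", "#f7f7f7", "#b2182b"))
  }
  rgb <- ramp(t)
  out[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  out
}

#' Render per-edge values onto the reference tree
#'
#' Writes (a) a CSV table of edge number, value and color, (b) a Newick
#' string in which every edge carries its color as a comment, and
#' optionally (c) an SVG heat-tree. Undefined edges (e.g. tip edges of an
#' imbalance-derived quantity) are rendered in a neutral gray.
#'
#' @param tree a [place_tree].
#' @param values per-edge values named by edge number (an `edge_values`
#'   object or plain named vector); edges absent from `values` are treated
#'   as undefined.
#' @param out_prefix path prefix; writes `<prefix>.csv`, `<prefix>.nwk`
#'   and, if requested, `<prefix>.svg`.
#' @param palette,center,log_scale passed to [map_colors()]; defaults to a
#'   divergent palette centered at 0 for correlation-like values and a
#'   sequential palette otherwise.
#' @param formats subset of `c("csv", "newick", "svg")`.
#' @return named character vector of written files, invisibly.
#' @export
render_tree <- function(tree, values, out_prefix,
                        palette = NULL, center = 0, log_scale = FALSE,
                        formats = c("csv", "newick")) {
  stopifnot(inherits(tree, "place_tree"))
  bad <- setdiff(formats, c("csv", "newick", "svg"))
  if (length(bad)) stop("unknown output format(s): ", paste(bad, collapse = ", "))
  if (is.null(palette)) {
    kind <- attr(values, "kind")
    palette <- if (!is.null(kind) && grepl("correlation|balance", kind)) {
      "divergent"
    } else {
      "sequential"
    }
  }
  full <- rep(NA_real_, n_edges(tree))
  names(full) <- tree$edge_num
  v_names <- names(values)
  if (is.null(v_names)) stop("`values` must be named by edge number")
  full[v_names] <- as.numeric(values)
  if (is.null(attr(values, "scale"))) attr(values, "scale") <- "linear"
  log_scale <- log_scale || identical(attr(values, "scale"), "log")
  cols <- map_colors(full, palette = palette, center = center,
                     log_scale = log_scale)
  written <- character(0)
  if ("csv" %in% formats) {
    df <- data.frame(edge_num = tree$edge_num, value = full, color = cols)
    df <- df[!is.na(df$value), ]
    f <- paste0(out_prefix, ".csv")
    write_csv_det(df, f)
    written["csv"] <- f
  }
  if ("newick" %in% formats) {
    phylo <- tree$phylo
    ntip <- length(phylo$tip.label)
    tag <- sprintf("[&!color=%s]", cols)
    lab <- character(ntip + phylo$Nnode)
    lab[phylo$edge[, 2]] <- tag
    phylo$tip.label <- paste0(phylo$tip.label, lab[seq_len(ntip)])
    phylo$node.label <- lab[(ntip + 1):(ntip + phylo$Nnode)]
    f <- paste0(out_prefix, ".nwk")
    ape::write.tree(phylo, file = f)
    written["newick"] <- f
  }
  if ("svg" %in% formats) {
    f <- paste0(out_prefix, ".svg")
    grDevices::svg(f, width = 7, height = 7)
    tryCatch(
      ape::plot.phylo(tree$phylo, edge.color = cols, edge.width = 2,
                      cex = 0.6, no.margin = TRUE),
      finally = grDevices::dev.off()
    )
    written["svg"] <- f
  }
  invisible(written)
}
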