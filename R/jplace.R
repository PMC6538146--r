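#' Convert per-branch log-likelihoods into likelihood weight ratios
#'
#' The raw likelihood scores of placing one query sequence into each
#' candidate branch are turned into probabilities by a numerically stable
#' softmax: `lwr_i = exp(l_i - max l) / sum_j exp(l_j - max l)`. The
#' resulting LWRs sum to 1 over all candidate branches.
#'
#' @param log_likelihoods numeric vector of finite log-likelihood scores.
#' @return numeric vector of LWRs, summing to 1.
#' @export
likelihoods_to_lwr <- function(log_likelihoods) {
  if (length(log_likelihoods) == 0) stop("need at least one likelihood score")
  if (any(!is.finite(log_likelihoods))) stop("log-likelihoods must be finite")
  w <- exp(log_likelihoods - max(log_likelihoods))
  w / sum(w)
}

#' Read a jplace file
#'
#' Parses jplace (versions 1-3) into a [place_sample]. Fields are mapped by
#' name, not position; both the `n` and `nm` pquery naming conventions are
#' accepted; edge numbers in the tree string may use the `{}` or `[]`
#' dialect. If only a `likelihood` field is present, LWRs are derived via
#' [likelihoods_to_lwr()]; if only `distal_length` is present, proximal
#' positions are derived as `branch_length - distal_length`.
#'
#' Pqueries whose LWRs sum to less than 1 are kept as-is by default: the
#' missing mass corresponds to discarded unlikely placements and is
#' meaningful. Set `renormalize = TRUE` to rescale each pquery to unit mass.
#'
#' @param path path to a jplace file.
#' @param name sample name; defaults to the file name without extension.
#' @param renormalize rescale each pquery's LWRs to sum to 1.
#' @return a [place_sample].
#' @export
read_jplace <- function(path, name = NULL, renormalize = FALSE) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("tree", "fields", "placements", "version")) {
    if (is.null(doc[[key]])) {
      stop(sprintf("jplace format error: mandatory field '%s' missing", key))
    }
  }
  version <- suppressWarnings(as.integer(doc$version))
  if (is.na(version) || !version %in% 1:3) {
    warning("unknown jplace version '", doc$version, "'; attempting best-effort parse")
  }
  tree <- parse_jplace_tree(doc$tree)
  fields <- unlist(doc$fields)
  if (!"edge_num" %in% fields) {
    stop("jplace format error: mandatory field 'edge_num' missing from fields")
  }
  has_lwr <- "like_weight_ratio" %in% fields
  if (!has_lwr && !"likelihood" %in% fields) {
    stop("jplace format error: need 'like_weight_ratio' or 'likelihood' field")
  }
  if (is.null(name)) {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  bl <- tree$phylo$edge.length
  col <- function(p_rows, field) {
    if (!field %in% fields) return(NULL)
    i <- match(field, fields)
    vapply(p_rows, function(r) as.numeric(r[[i]]), numeric(1))
  }
  query_names <- list()
  multiplicity <- numeric(0)
  plc <- list()
  for (qi in seq_along(doc$placements)) {
    pq <- doc$placements[[qi]]
    if (!is.null(pq$nm)) {
      nm <- vapply(pq$nm, function(x) as.character(x[[1]]), character(1))
      mult <- sum(vapply(pq$nm, function(x) as.numeric(x[[2]]), numeric(1)))
    } else if (!is.null(pq$n)) {
      nm <- unlist(pq$n)
      mult <- 1.0
    } else {
      stop("jplace format error: pquery without 'n' or 'nm' names")
    }
    edge_num <- col(pq$p, "edge_num")
    lwr <- if (has_lwr) {
      col(pq$p, "like_weight_ratio")
    } else {
      likelihoods_to_lwr(col(pq$p, "likelihood"))
    }
    if (renormalize && sum(lwr) > 0) lwr <- lwr / sum(lwr)
    rows <- edge_row(tree, edge_num)
    prox <- col(pq$p, "proximal_length")
    if (is.null(prox)) {
      dist <- col(pq$p, "distal_length")
      prox <- if (is.null(dist)) bl[rows] / 2 else bl[rows] - dist
    }
    pend <- col(pq$p, "pendant_length")
    if (is.null(pend)) pend <- rep(0, length(edge_num))
    query_names[[qi]] <- nm
    multiplicity[qi] <- mult
    plc[[qi]] <- data.frame(
      query = qi, edge_num = as.integer(edge_num), like_weight_ratio = lwr,
      proximal_length = prox, pendant_length = pend
    )
  }
  placements <- if (length(plc)) {
    do.call(rbind, plc)
  } else {
    data.frame(
      query = integer(0), edge_num = integer(0), like_weight_ratio = numeric(0),
      proximal_length = numeric(0), pendant_length = numeric(0)
    )
  }
  place_sample(name, tree, query_names, multiplicity, placements)
}

#' Write a sample to a jplace file
#'
#' Writes jplace version 3 with fields `edge_num`, `like_weight_ratio`,
#' `proximal_length`, `pendant_length` and `nm`-style pquery names. Floats
#' are written with enough digits to round-trip bit-comparably, so
#' `read_jplace(write_jplace(s))` reproduces masses and topology exactly.
#'
#' @param sample a [place_sample].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_jplace <- function(sample, path) {
  pl <- sample$placements
  pqueries <- lapply(seq_len(n_queries(sample)), function(qi) {
    rows <- pl[pl$query == qi, ]
    nms <- sample$query_names[[qi]]
    mult <- sample$multiplicity[qi] / length(nms)
    list(
      p = lapply(seq_len(nrow(rows)), function(i) {
        list(
          as.integer(rows$edge_num[i]), rows$like_weight_ratio[i],
          rows$proximal_length[i], rows$pendant_length[i]
        )
      }),
      nm = lapply(nms, function(nm) list(nm, mult))
    )
  })
  doc <- list(
    version = 3L,
    tree = write_jplace_tree(sample$tree),
    fields = list("edge_num", "like_weight_ratio", "proximal_length", "pendant_length"),
    placements = pqueries,
    metadata = list(invocation = "placemass::write_jplace")
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17))
  tryCatch(
    writeLines(json, path),
    error = function(e) stop("cannot write jplace file to '", path, "': ", conditionMessage(e))
  )
  invisible(path)
}

#' Read a per-sample meta-data table
#'
#' Reads a CSV/TSV table with one row per sample, reorders the rows to the
#' given sample order, parses fully numeric columns as numbers and keeps the
#' rest as factors (categorical features).
#'
#' @param path CSV or TSV file with a header row.
#' @param sample_names character vector giving the required sample order.
#' @param key name of the column holding sample names; defaults to a column
#'   named `sample`, else the first column.
#' @param sep field separator; guessed from the file extension by default.
#' @param on_missing what to do when a sample has no meta-data row:
#'   `"error"` (default) or `"drop"` (returns table without that sample, with
#'   a warning).
#' @return data.frame with `rownames` = sample names, columns = features.
#' @export
read_metadata <- function(path, sample_names, key = NULL, sep = NULL,
                          on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(
    path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
    check.names = FALSE
  )
  if (is.null(key)) {
    key <- if ("sample" %in% names(tab)) "sample" else names(tab)[1]
  }
  if (!key %in% names(tab)) stop("key column '", key, "' not found in meta-data table")
  keys <- as.character(tab[[key]])
  idx <- match(sample_names, keys)
  if (anyNA(idx)) {
    missing <- sample_names[is.na(idx)]
    if (on_missing == "error") {
      stop("no meta-data for sample(s): ", paste(missing, collapse = ", "))
    }
    warning("dropping sample(s) without meta-data: ", paste(missing, collapse = ", "))
    sample_names <- sample_names[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  out <- tab[idx, setdiff(names(tab), key), drop = FALSE]
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      out[[j]] <- if (all(is.na(num) == is.na(v))) num else factor(v)
    }
  }
  rownames(out) <- sample_names
  out
}
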