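# fixture builders and independent oracles shared across the test suite

# hand-built 4-taxon reference tree with known edge numbers:
# ((A:1{0},B:1{1}):1{2},C:1{3},D:1{4});
small_tree <- function() {
  placemass:::parse_jplace_tree("((A:1{0},B:1{1}):1{2},C:1{3},D:1{4});")
}

# a place_sample from a compact placement table (one unit-multiplicity
# pquery per row group; columns edge_num, lwr, pos)
make_sample <- function(tree, df, multiplicity = NULL, name = "s") {
  nq <- max(df$query)
  if (is.null(multiplicity)) multiplicity <- rep(1, nq)
  if (is.null(df$proximal_length)) df$proximal_length <- 0
  if (is.null(df$pendant_length)) df$pendant_length <- 0
  place_sample(
    name, tree,
    query_names = as.list(paste0("q", seq_len(nq))),
    multiplicity = multiplicity,
    placements = df
  )
}

# jplace document text with configurable field order / dialects
jplace_text <- function(tree = "((A:0.2{0},B:0.09{1}):0.7{2},C:0.5{3});",
                        fields = c("edge_num", "like_weight_ratio",
                                   "proximal_length", "pendant_length"),
                        pqueries, version = 3) {
  sprintf(
    '{"version": %d, "tree": "%s", "fields": [%s], "placements": [%s]}',
    version, tree,
    paste(sprintf('"%s"', fields), collapse = ", "),
    paste(pqueries, collapse = ", ")
  )
}

write_jplace_text <- function(..., file = tempfile(fileext = ".jplace")) {
  writeLines(jplace_text(...), file)
  file
}

# O(m^2) brute-force edge imbalances: per edge, re-sum both partitions,
# with the distal side found by BFS over the edge table (independent of
# the package's preorder-span bookkeeping)
brute_imbalances <- function(mass, tree, include_tips = FALSE) {
  phylo <- tree$phylo
  m <- nrow(phylo$edge)
  total <- sum(mass)
  out <- numeric(m)
  for (i in seq_len(m)) {
    distal <- numeric(0)
    frontier <- phylo$edge[i, 2]
    while (length(frontier)) {
      rows <- which(phylo$edge[, 1] %in% frontier)
      distal <- c(distal, rows)
      frontier <- phylo$edge[rows, 2]
    }
    out[i] <- (total - mass[i] - sum(mass[distal])) - sum(mass[distal])
  }
  names(out) <- tree$edge_num
  if (!include_tips) out <- out[!tree$tip_edge]
  out
}

# independent tree-path distance between two mass points, via the node
# distance matrix of ape::dist.nodes; a point is (edge row, proximal pos)
point_path_dist <- function(tree, ei, pi_, ej, pj_) {
  phylo <- tree$phylo
  D <- ape::dist.nodes(phylo)
  len <- phylo$edge.length
  if (ei == ej) return(abs(pi_ - pj_))
  ends_i <- phylo$edge[ei, ] # parent, child; pos measured from parent
  ends_j <- phylo$edge[ej, ]
  off_i <- c(pi_, len[ei] - pi_)
  off_j <- c(pj_, len[ej] - pj_)
  best <- Inf
  for (a in 1:2) {
    for (b in 1:2) {
      best <- min(best, off_i[a] + D[ends_i[a], ends_j[b]] + off_j[b])
    }
  }
  best
}

# exact earth-mover distance by linear programming (scipy.optimize.linprog
# as the external reference); instances: list of list(cost, a, b)
lp_emd <- function(instances) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- lapply(instances, function(x) {
    list(cost = unname(as.matrix(x$cost)), a = x$a, b = x$b)
  })
  jsonlite::write_json(payload, infile, digits = NA, auto_unbox = FALSE)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
with open(sys.argv[1]) as fh:
    cases = json.load(fh)
res = []
for case in cases:
    C = np.asarray(case["cost"], dtype=float)
    a = np.asarray(case["a"], dtype=float)
    b = np.asarray(case["b"], dtype=float)
    na, nb = C.shape
    Aeq = []
    for i in range(na):
        row = np.zeros((na, nb)); row[i, :] = 1; Aeq.append(row.ravel())
    for j in range(nb):
        row = np.zeros((na, nb)); row[:, j] = 1; Aeq.append(row.ravel())
    beq = np.concatenate([a, b])
    sol = linprog(C.ravel(), A_eq=np.asarray(Aeq), b_eq=beq,
                  bounds=(0, None), method="highs")
    assert sol.status == 0, sol.message
    res.append(float(sol.fun))
with open(sys.argv[2], "w") as fh:
    json.dump(res, fh)
'
  scriptfile <- tempfile(fileext = ".py")
  writeLines(script, scriptfile)
  status <- system2("python", c(scriptfile, infile, outfile))
  stopifnot(status == 0)
  unlist(jsonlite::fromJSON(outfile))
}

# KR distance of two mass_points objects via the LP oracle
lp_kr <- function(mp_a, mp_b) {
  tree <- mp_a$tree
  pts <- function(mp) {
    do.call(rbind, lapply(seq_along(mp$pos), function(i) {
      if (!length(mp$pos[[i]])) return(NULL)
      cbind(edge = i, pos = mp$pos[[i]], mass = mp$mass[[i]])
    }))
  }
  A <- pts(mp_a)
  B <- pts(mp_b)
  cost <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      cost[i, j] <- point_path_dist(tree, A[i, 1], A[i, 2], B[j, 1], B[j, 2])
    }
  }
  lp_emd(list(list(cost = cost, a = A[, 3], b = B[, 3])))[1]
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# edge rows of k mutually disjoint inner clades (smallest eligible first)
disjoint_clades <- function(tree, k, min_span = 3) {
  inner <- which(!tree$tip_edge)
  for (ms in seq(min_span, 2)) {
    cands <- inner[tree$span[inner] >= ms]
    cands <- cands[order(tree$span[cands])]
    picks <- integer(0)
    covered <- integer(0)
    for (e in cands) {
      clade <- c(e, e + seq_len(tree$span[e]))
      if (!length(intersect(clade, covered))) {
        picks <- c(picks, e)
        covered <- c(covered, clade)
      }
      if (length(picks) == k) return(picks)
    }
  }
  stop("tree has no ", k, " disjoint inner clades")
}

# planted two-group clustering fixture: one clade per group
planted_partition_fixture <- function(n_per_group = 20, taxa = 16,
                                      fraction = 0.85, seed = 1,
                                      n_queries = 60) {
  tree <- random_tree(taxa, seed = seed)
  picks <- disjoint_clades(tree, 2)
  e1 <- picks[1]
  e2 <- picks[2]
  group <- rep(c("A", "B"), each = n_per_group)
  fix <- simulate_samples(
    tree, n_samples = 2 * n_per_group, n_queries = n_queries,
    planted = list(
      list(edge_num = tree$edge_num[e1],
           fraction = ifelse(group == "A", fraction, 0.02), feature = FALSE),
      list(edge_num = tree$edge_num[e2],
           fraction = ifelse(group == "B", fraction, 0.02), feature = FALSE)
    ),
    group = group, seed = seed
  )
  fix$group <- group
  fix
}
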