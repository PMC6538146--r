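test_that("the GLM objective is the deviance reduction of the fit", {
  z <- data.frame(x = c(1, 2, 3, 4, 5, 6))
  # perfectly linear contrasts: residual deviance 0, omega = null deviance
  ctr <- 2 * z$x - 3
  omega <- glm_objective(ctr, z)
  expect_equal(omega, sum((ctr - mean(ctr))^2), tolerance = 1e-9)
  # constant contrasts carry no signal
  expect_equal(glm_objective(rep(1.5, 6), z), 0)
  # random case against an independent least-squares oracle
  set.seed(3)
  Z <- data.frame(x = stats::rnorm(20), g = factor(rep(c("u", "v"), 10)))
  ctr2 <- stats::rnorm(20)
  fit <- stats::lm(ctr2 ~ x + g, data = Z)
  expect_equal(glm_objective(ctr2, Z),
               sum((ctr2 - mean(ctr2))^2) - sum(stats::resid(fit)^2),
               tolerance = 1e-9)
  # fewer complete cases than parameters: undefined
  Zs <- data.frame(x = c(1, 2, NA, NA, NA, NA), y = c(2, 1, 1, 1, 1, 3))
  expect_true(is.na(glm_objective(ctr, Zs)))
})

planted_factor_fixture <- function(seed, taxa = 14, n_samples = 20,
                                   noise_sd = 0.02) {
  tree <- random_tree(taxa, seed = seed)
  e <- disjoint_clades(tree, 1)
  fix <- simulate_samples(
    tree, n_samples = n_samples, n_queries = 60,
    planted = list(list(edge_num = tree$edge_num[e],
                        fraction = c(0.05, 0.7), noise_sd = noise_sd)),
    seed = seed
  )
  fix$planted_row <- e
  fix
}

# edge rows on the path between a planted clade and the root: the clade
# itself plus all its ancestors
planted_path_rows <- function(tree, e) {
  ancestors <- which(vapply(seq_len(n_edges(tree)), function(i) {
    e %in% (i + seq_len(tree$span[i]))
  }, logical(1)))
  c(e, e + seq_len(tree$span[e]), ancestors)
}

test_that("factor 1 recovers a planted meta-data-driven clade", {
  hits <- 0L
  for (seed in 1:10) {
    fix <- planted_factor_fixture(seed)
    pf <- placement_factorization(fix$samples, fix$metadata, iterations = 1)
    winner <- pf$factors[[1]]$edge_num
    path <- fix$tree$edge_num[planted_path_rows(fix$tree, fix$planted_row)]
    if (winner %in% path) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("a nested planted clade is recovered as a later factor", {
  found <- 0L
  for (seed in c(2, 5, 8)) {
    tree <- random_tree(24, seed = seed)
    # outer clade with a genuinely nested inner clade
    inner_edges <- which(!tree$tip_edge)
    outer <- inner_edges[tree$span[inner_edges] >= 10][1]
    sub <- outer + seq_len(tree$span[outer])
    nested_cands <- sub[!tree$tip_edge[sub] & tree$span[sub] >= 2 &
                          tree$span[sub] <= floor(tree$span[outer] / 2) - 1]
    nested <- nested_cands[length(nested_cands)] # smallest, deepest clade
    fix <- simulate_samples(
      tree, n_samples = 24, n_queries = 80,
      planted = list(
        list(edge_num = tree$edge_num[outer], fraction = c(0.1, 0.5),
             noise_sd = 0.02),
        list(edge_num = tree$edge_num[nested], fraction = c(0.05, 0.3),
             noise_sd = 0.02)
      ),
      seed = seed
    )
    pf <- placement_factorization(fix$samples, fix$metadata, iterations = 3)
    winners <- vapply(pf$factors, `[[`, integer(1), "edge_num")
    nested_path <- tree$edge_num[planted_path_rows(tree, nested)]
    if (any(winners[-1] %in% nested_path)) found <- found + 1L
  }
  expect_gte(found, 2L)
})

test_that("objective values are non-negative and winners are distinct", {
  fix <- planted_factor_fixture(4)
  pf <- placement_factorization(fix$samples, fix$metadata, iterations = 4)
  winners <- vapply(pf$factors, `[[`, integer(1), "edge_num")
  expect_equal(anyDuplicated(winners), 0L)
  for (f in pf$factors) {
    expect_true(all(f$objective >= 0, na.rm = TRUE))
    expect_equal(
      unname(f$objective[as.character(f$edge_num)]),
      max(f$objective, na.rm = TRUE)
    )
    # contrasts only use edges inside the winning edge's subtree
    expect_length(intersect(f$R, f$S), 0)
    expect_false(f$edge_num %in% c(f$R, f$S))
  }
})

test_that("i iterations split the non-winner edges into i + 1 subtrees", {
  tree <- random_tree(10, seed = 12)
  fix <- simulate_samples(
    tree, n_samples = 12, n_queries = 40,
    planted = list(list(edge_num = tree$edge_num[disjoint_clades(tree, 1)],
                        fraction = c(0.1, 0.6), noise_sd = 0.05)),
    seed = 12
  )
  n_cand <- sum(!tree$tip_edge) # tip edges are never factors
  pf <- suppressWarnings(
    placement_factorization(fix$samples, fix$metadata, iterations = n_cand)
  )
  i <- length(pf$factors)
  comp <- pf$components
  winners <- vapply(pf$factors, `[[`, integer(1), "edge_num")
  expect_equal(sum(comp == 0), i)
  expect_setequal(names(comp)[comp == 0], as.character(winners))
  # non-winner edges fall into i + 1 disjoint subtrees
  expect_equal(length(unique(comp[comp > 0])), i + 1L)
})

test_that("winning-edge choice ignores the labels of a two-level factor", {
  fix <- planted_partition_fixture(n_per_group = 8, taxa = 12, seed = 41,
                                   n_queries = 40)
  meta1 <- data.frame(group = factor(fix$group))
  meta2 <- data.frame(group = factor(ifelse(fix$group == "A", "zeta", "eta")))
  pf1 <- placement_factorization(fix$samples, meta1, iterations = 2)
  pf2 <- placement_factorization(fix$samples, meta2, iterations = 2)
  expect_equal(
    vapply(pf1$factors, `[[`, integer(1), "edge_num"),
    vapply(pf2$factors, `[[`, integer(1), "edge_num")
  )
})

test_that("the factorization is deterministic for a fixed input", {
  fix <- planted_factor_fixture(6, n_samples = 12)
  a <- placement_factorization(fix$samples, fix$metadata, iterations = 2)
  b <- placement_factorization(fix$samples, fix$metadata, iterations = 2)
  expect_identical(
    lapply(a$factors, `[[`, "objective"),
    lapply(b$factors, `[[`, "objective")
  )
})

test_that("the balance ordination reproduces and scales the contrasts", {
  fix <- planted_partition_fixture(n_per_group = 8, taxa = 12, seed = 51,
                                   n_queries = 40)
  meta <- data.frame(group = factor(fix$group))
  pf <- placement_factorization(fix$samples, meta, iterations = 1)
  ord <- factor_ordination(pf)
  expect_equal(ncol(ord), 1L)
  expect_equal(ord[[1]], unname(pf$factors[[1]]$contrasts))
  # groups separate by the sign of the factor-1 balances
  ari <- adjusted_rand(ord[[1]] > stats::median(ord[[1]]), fix$group)
  expect_equal(ari, 1.0)
  sc <- factor_ordination(pf, scale = TRUE)
  expect_equal(max(abs(sc[[1]])), 1.0, tolerance = 1e-12)
  expect_equal(sign(sc[[1]]), sign(ord[[1]]))
})

test_that("objective maps color candidates and leave the rest neutral", {
  fix <- planted_factor_fixture(9, n_samples = 12)
  pf <- placement_factorization(fix$samples, fix$metadata, iterations = 2)
  prefix <- tempfile()
  files <- objective_map(pf, 2, prefix)
  csv <- utils::read.csv(files["csv"])
  f2 <- pf$factors[[2]]
  # tip edges and the previous winner are absent from the map
  expect_false(pf$factors[[1]]$edge_num %in% csv$edge_num)
  tips <- edge_numbers(fix$tree)[fix$tree$tip_edge]
  expect_length(intersect(csv$edge_num, tips), 0)
  expect_equal(
    csv$value[csv$edge_num == f2$edge_num],
    max(csv$value), tolerance = 1e-12
  )
  expect_error(objective_map(pf, 5, prefix), "range")
})
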