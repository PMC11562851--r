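test_that("two-node chain matches the closed-form fixed point", {
  net <- load_net("1", "2")
  for (r in c(0.15, 0.5, 0.8, 0.85)) {
    s <- personalized_pagerank(net, "1", ppr_params(restart = r))
    ## s(seed) = 1/(2 - r) from solving the 2x2 system by hand
    expect_equal(unname(s[["1"]]), 1 / (2 - r), tolerance = 1e-9)
    expect_equal(unname(s[["2"]]), (1 - r) / (2 - r), tolerance = 1e-9)
  }
})

test_that("scores are a probability vector with the expected symmetries", {
  ## complete graph on 4 nodes: the three non-seed nodes are exchangeable
  e <- t(combn(as.character(1:4), 2))
  net <- load_net(e[, 1], e[, 2])
  s <- personalized_pagerank(net, "1")
  expect_equal(sum(s), 1, tolerance = 1e-8)
  expect_true(all(s >= 0))
  expect_equal(unname(s[["2"]]), unname(s[["3"]]), tolerance = 1e-10)
  expect_equal(unname(s[["3"]]), unname(s[["4"]]), tolerance = 1e-10)
  ## restart -> 1 collapses onto the seed
  s1 <- personalized_pagerank(net, "1", ppr_params(restart = 1 - 1e-9))
  expect_equal(unname(s1[["1"]]), 1, tolerance = 1e-6)
})

test_that("power iteration agrees with a direct linear solve and igraph", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    ed <- random_edges(n, 0.12)
    net <- load_net(ed$from, ed$to)
    seed <- sample(net$nodes, 1)
    r <- sample(c(0.2, 0.8), 1)
    mine <- personalized_pagerank(net, seed, ppr_params(restart = r))
    oracle <- ppr_solve_oracle(net, seed, r)
    expect_lt(max(abs(mine - oracle[names(mine)])), 1e-8)
    ## independent implementation: igraph's personalized PageRank with
    ## damping = 1 - restart
    g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = net$nodes)
    reset <- as.numeric(net$nodes == seed)
    ig <- igraph::page_rank(g, damping = 1 - r, personalized = reset)$vector
    expect_lt(max(abs(mine - ig[names(mine)])), 1e-6)
  }
})

test_that("scores are invariant to node relabeling", {
  set.seed(5)
  ed <- random_edges(15, 0.2)
  net1 <- load_net(ed$from, ed$to)
  relab <- setNames(as.character(as.numeric(ed$from) + 500), NULL)
  net2 <- load_net(as.character(as.numeric(ed$from) + 500),
                   as.character(as.numeric(ed$to) + 500))
  s1 <- personalized_pagerank(net1, "1")
  s2 <- personalized_pagerank(net2, "501")
  expect_equal(unname(s1[order(as.numeric(names(s1)))]),
               unname(s2[order(as.numeric(names(s2)))]),
               tolerance = 1e-10)
})

test_that("seed membership and convergence failures raise clear errors", {
  net <- load_net("1", "2")
  expect_error(personalized_pagerank(net, "99"), "99")
  expect_error(personalized_pagerank(net, "1", ppr_params(max_iter = 1)),
               "converge")
})

test_that("pathway_score is the arithmetic mean over members", {
  s <- c(A = 0.5, B = 0.3, C = 0.2)
  expect_equal(pathway_score(s, c("B", "C")), 0.25)
  expect_equal(pathway_score(s, "B"), 0.3)
  expect_equal(pathway_score(s, names(s)), 1 / 3)  # all nodes -> 1/|V|
  expect_error(pathway_score(s, character()), "no members")
  expect_error(pathway_score(s, c("B", "Z")), "Z")
  ## adding a higher-scoring member never decreases the mean
  expect_gte(pathway_score(s, c("B", "C", "A")), pathway_score(s, c("B", "C")))
})

test_that("permutation p-values hit both extremes on a symmetric cycle", {
  ## on a cycle every node has degree 2 -> a single degree bin; the
  ## seed's two neighbors get the highest scores of all, so the observed
  ## mean beats every permuted seed; two antipodal nodes get the lowest
  n <- 24
  from <- as.character(1:n)
  to <- as.character(c(2:n, 1))
  net <- suppressWarnings(assign_degree_bins(load_net(from, to)))
  params <- ppr_params(n_perm = 200, rng_seed = 99)
  ## observed beats every permutation: the seed's own score dominates any
  ## other node's score of it
  top <- permutation_p(net, "1", "1", params, "self")
  expect_equal(top$perm_count_ge, 0L)
  expect_equal(top$p_perm, 1 / 201)  # add-one estimator at the extreme
  expect_equal(top$p_raw, 0)
  ## observed below every permutation: the antipodal seed is strictly the
  ## farthest node from both members
  far <- permutation_p(net, "13", c("2", "24"), params, "far")
  expect_equal(far$p_perm, 1)
  expect_equal(far$p_raw, 1)
})

test_that("permutation p matches exhaustive enumeration over the degree bin", {
  set.seed(31)
  ed <- random_edges(30, 0.15)
  net <- suppressWarnings(assign_degree_bins(load_net(ed$from, ed$to)))
  members <- sample(net$nodes, 6)
  seed <- sample(setdiff(net$nodes, members), 1)
  n_perm <- 400
  res <- permutation_p(net, seed, members, ppr_params(n_perm = n_perm,
                                                      rng_seed = 7), "pw")
  ## oracle: score every bin member directly and compute the exact
  ## probability a uniform draw ties or beats the observed mean
  bin <- net$degree_bin[[seed]]
  pool <- setdiff(names(net$degree_bin)[net$degree_bin == bin], seed)
  if (length(pool) == 0) skip("degenerate pool")
  obs <- pathway_score(personalized_pagerank(net, seed), members)
  pool_means <- vapply(pool, function(g)
    pathway_score(personalized_pagerank(net, g), members), numeric(1))
  f <- mean(pool_means >= obs)
  mc_sd <- sqrt(f * (1 - f) / n_perm)
  expect_lt(abs(res$p_raw - f), 4 * mc_sd + 1e-9)
})

test_that("small-bin seeds fall back to the nearest bin with a warning", {
  ## star graph: the hub is alone in the top bin
  net <- load_net(rep("100", 8), as.character(1:8))
  net <- suppressWarnings(assign_degree_bins(net))
  expect_warning(
    res <- permutation_p(net, "100", c("1", "2"), ppr_params(n_perm = 50)),
    "falling back")
  expect_equal(nrow(res), 1)
})

test_that("linkage tables are deterministic and order-independent", {
  set.seed(13)
  ed <- random_edges(60, 0.08)
  net <- suppressWarnings(assign_degree_bins(load_net(ed$from, ed$to)))
  sets <- list(PA = sample(net$nodes, 8), PB = sample(net$nodes, 5),
               PC = sample(net$nodes, 10))
  pc <- structure(list(sets = sets,
                       description = setNames(rep("", 3), names(sets))),
                  class = "pathway_collection")
  seeds <- sample(net$nodes, 3)
  params <- ppr_params(n_perm = 100, rng_seed = 17)
  t1 <- link_seeds_to_pathways(net, seeds, pc, params)
  t2 <- link_seeds_to_pathways(net, rev(seeds), pc, params)
  data.table::setorder(t1, seed, pathway)
  data.table::setorder(t2, seed, pathway)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  ## Bonferroni bookkeeping: m = |seeds| x |pathways|
  expect_equal(t1$p_adj, pmin(1, t1$p_perm * 9))
  expect_equal(t1$p_raw_adj, pmin(1, t1$p_raw * 9))
  expect_true(all(t1$p_perm > 0 & t1$p_perm <= 1))
  expect_true(all(t1$perm_count_ge >= 0 & t1$perm_count_ge <= 100))
  ## single-pair results match the standalone operation
  single <- permutation_p(net, seeds[1], sets$PA, params, "PA")
  row <- t1[t1$seed == seeds[1] & t1$pathway == "PA", ]
  expect_equal(row$observed, single$observed)
  expect_equal(row$perm_count_ge, single$perm_count_ge)
})

test_that("seeds outside the network are dropped with a warning", {
  net <- suppressWarnings(assign_degree_bins(load_net(c("1", "2"), c("2", "3"))))
  pc <- structure(list(sets = list(P = c("1", "3")),
                       description = c(P = "")),
                  class = "pathway_collection")
  expect_warning(
    tab <- link_seeds_to_pathways(net, c("1", "999"), pc,
                                  ppr_params(n_perm = 20)),
    "999")
  expect_equal(unique(tab$seed), "1")
  ## empty seed set -> empty table
  empty <- link_seeds_to_pathways(net, character(), pc, ppr_params(n_perm = 20))
  expect_equal(nrow(empty), 0)
})

test_that("target-stage Bonferroni family is the number of targets tested", {
  set.seed(14)
  ed <- random_edges(40, 0.12)
  net <- suppressWarnings(assign_degree_bins(load_net(ed$from, ed$to)))
  pc <- structure(list(sets = list(P = sample(net$nodes, 6)),
                       description = c(P = "")),
                  class = "pathway_collection")
  targets <- sample(net$nodes, 4)
  params <- ppr_params(n_perm = 50, rng_seed = 2)
  tab <- link_targets_to_pathways(net, targets, pc, params)
  expect_equal(tab$p_adj, pmin(1, tab$p_perm * 4))
  ## explicit family override (family spans targets beyond this call)
  tab10 <- link_targets_to_pathways(net, targets, pc, params, family_size = 10)
  expect_equal(tab10$p_adj, pmin(1, tab10$p_perm * 10))
  ## a target appearing in two drugs is computed once per gene: identical
  ## substreams give identical rows
  expect_equal(tab$perm_count_ge, tab10$perm_count_ge)
})
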