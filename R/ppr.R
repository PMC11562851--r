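#' Parameters for personalized-PageRank linkage
#'
#' @param restart probability of returning to the seed gene at each step
#'   of the random walk (default 0.8, the propagation default used for
#'   this statistic; note this is the restart probability, not the
#'   PageRank damping/continue probability).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter maximum power iterations before failing.
#' @param n_perm number of permutation draws for the null (default 1000).
#' @param rng_seed integer seed from which per-(seed, pathway) RNG
#'   substreams are derived; results are independent of evaluation order.
#' @param include_seed when the seed gene is itself a pathway member,
#'   include its own score in the pathway mean (default TRUE).
#' @return list of class `ppr_params`.
#' @export
ppr_params <- function(restart = 0.8, tol = 1e-10, max_iter = 1000,
                       n_perm = 1000, rng_seed = 1, include_seed = TRUE) {
  stopifnot(is.numeric(restart), length(restart) == 1, restart > 0, restart < 1,
            n_perm >= 1, max_iter >= 1, tol > 0)
  structure(list(restart = restart, tol = tol, max_iter = as.integer(max_iter),
                 n_perm = as.integer(n_perm), rng_seed = as.integer(rng_seed),
                 include_seed = isTRUE(include_seed)),
            class = "ppr_params")
}

## Power iteration on the node-index scale. Returns an unnamed numeric
## vector over net$nodes. The fixed point solved is
##   s = restart * e_seed + (1 - restart) * t(W) s,   W = D^{-1} A,
## for the undirected, unweighted, confidence-filtered adjacency A. A
## zero-degree node cannot arise from an edge-built network, but if one
## does its walk mass teleports back to the seed.
.ppr_power <- function(net, seed_idx, params) {
  n <- length(net$nodes)
  A <- net$adjacency
  deg <- as.numeric(net$degree)
  r <- params$restart
  e <- numeric(n); e[seed_idx] <- 1
  x <- e
  dangling <- deg == 0
  inv_deg <- ifelse(dangling, 0, 1 / deg)
  for (it in seq_len(params$max_iter)) {
    spread <- as.numeric(A %*% (x * inv_deg))
    if (any(dangling)) spread[seed_idx] <- spread[seed_idx] + sum(x[dangling])
    x_new <- r * e + (1 - r) * spread
    if (sum(abs(x_new - x)) < params$tol) return(x_new)
    x <- x_new
  }
  stop(sprintf("personalized PageRank did not converge after %d iterations (residual %.3g)",
               params$max_iter, sum(abs(x_new - x))))
}

#' Personalized PageRank scores from a seed gene
#'
#' Stationary distribution of a random walk on the PPI network that, at
#' each step, returns to the seed gene with probability `restart` and
#' otherwise moves to a uniformly chosen neighbor. Scores are
#' non-negative, sum to one, and measure each gene's connectivity to the
#' seed. Solved deterministically by power iteration.
#'
#' @param net a `ppi_network`.
#' @param seed Entrez ID of the seed gene (must be in the network).
#' @param params a [ppr_params()] object.
#' @return named numeric vector over all network nodes.
#' @export
personalized_pagerank <- function(net, seed, params = ppr_params()) {
  stopifnot(inherits(net, "ppi_network"))
  seed <- as.character(seed)
  idx <- match(seed, net$nodes)
  if (is.na(idx)) stop(sprintf("seed gene '%s' is not in the network", seed))
  setNames(.ppr_power(net, idx, params), net$nodes)
}

#' Mean PPR score over a pathway's members
#'
#' @param scores named score vector from [personalized_pagerank()].
#' @param members character vector of pathway member Entrez IDs (already
#'   restricted to the network).
#' @return arithmetic mean of the members' scores.
#' @export
pathway_score <- function(scores, members) {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("pathway has no members")
  if (!all(members %in% names(scores))) {
    stop("pathway members missing from the score vector: ",
         paste(head(setdiff(members, names(scores)), 3), collapse = ", "))
  }
  mean(scores[members])
}

## --- internal permutation machinery ------------------------------------

## Sparse row-normalized membership matrix: n_pathways x n_nodes with
## 1/|P| entries, so M %*% s yields every pathway mean in one product.
.pathway_matrix <- function(net, sets) {
  idx <- setNames(seq_along(net$nodes), net$nodes)
  rows <- rep(seq_along(sets), vapply(sets, length, integer(1)))
  cols <- idx[unlist(sets, use.names = FALSE)]
  if (anyNA(cols)) stop("pathway member absent from network; restrict first")
  vals <- 1 / vapply(sets, length, numeric(1))[rows]
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(length(sets), length(net$nodes)),
                       dimnames = list(names(sets), NULL))
}

## PPR vector for a node index, memoised in `cache` (an environment).
.ppr_cached <- function(net, idx, params, cache) {
  key <- as.character(idx)
  v <- cache[[key]]
  if (is.null(v)) {
    v <- .ppr_power(net, idx, params)
    cache[[key]] <- v
  }
  v
}

## Permutation pool for a seed: same-degree-bin node indices, the seed
## itself excluded. Falls back to the nearest non-empty bin (by bin label
## distance) when the seed's bin has fewer than 2 members.
.perm_pool <- function(net, seed_idx) {
  if (is.null(net$degree_bin)) stop("degree bins not assigned; call assign_degree_bins()")
  bins <- net$degree_bin
  b <- bins[[seed_idx]]
  pool <- which(bins == b)
  pool <- pool[pool != seed_idx]
  if (length(pool) < 1) {
    others <- sort(unique(bins[bins != b]))
    if (length(others) == 0) stop("no permutation candidates in any degree bin")
    nb <- others[which.min(abs(others - b))]
    warning(sprintf("degree bin %d too small; falling back to nearest bin %d", b, nb))
    pool <- which(bins == nb)
    pool <- pool[pool != seed_idx]
  }
  pool
}

#' Degree-matched permutation test for one seed-pathway pair
#'
#' Computes the observed mean PPR score of `members` from `seed`, then
#' draws `n_perm` genes with replacement from the seed's degree bin (seed
#' excluded), scores the pathway from each, and reports how the observed
#' mean ranks in that null. Two empirical p-values are returned: `p_raw`
#' = c/N, the plain frequency of permuted means at or above the observed
#' one (this is what the staged Bonferroni decision uses and it can reach
#' zero), and `p_perm` = (1+c)/(1+N), the add-one estimator, a
#' conservative never-zero bound. The RNG substream is derived from
#' `(rng_seed, seed, pathway_name)` so results do not depend on
#' evaluation order.
#'
#' @param net a `ppi_network` with degree bins assigned.
#' @param seed seed gene Entrez ID.
#' @param members pathway member Entrez IDs (network-restricted).
#' @param params a [ppr_params()].
#' @param pathway_name label used in the RNG substream key and the output.
#' @param cache optional environment memoising PPR vectors across calls
#'   (pass the same environment when testing many pairs on one network).
#' @return one-row data.table: `seed`, `pathway`, `observed`,
#'   `perm_count_ge`, `p_perm`, `p_raw`.
#' @export
permutation_p <- function(net, seed, members, params = ppr_params(),
                          pathway_name = "pathway", cache = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  seed <- as.character(seed)
  seed_idx <- match(seed, net$nodes)
  if (is.na(seed_idx)) stop(sprintf("seed gene '%s' is not in the network", seed))
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  members <- unique(as.character(members))
  if (!params$include_seed) members <- setdiff(members, seed)
  midx <- match(members, net$nodes)
  if (anyNA(midx)) stop("pathway members missing from network")
  if (length(midx) == 0) stop("pathway has no members")

  obs <- mean(.ppr_cached(net, seed_idx, params, cache)[midx])
  pool <- .perm_pool(net, seed_idx)
  draws <- .pd_with_seed(
    .pd_stream_seed(params$rng_seed, seed, pathway_name),
    sample(pool, params$n_perm, replace = TRUE))
  uniq <- unique(draws)
  means <- vapply(uniq, function(i) mean(.ppr_cached(net, i, params, cache)[midx]),
                  numeric(1))
  perm <- means[match(draws, uniq)]
  cnt <- sum(perm >= obs)
  data.table::data.table(
    seed = seed, pathway = pathway_name, observed = obs,
    perm_count_ge = as.integer(cnt),
    p_perm = (1 + cnt) / (1 + params$n_perm),
    p_raw = cnt / params$n_perm)
}

## Shared worker for both linkage stages. `m_family` is the Bonferroni
## family size. Returns the full LinkageResult table.
.link_stage <- function(net, seeds, pathways, params, m_family,
                        ppr_cache = NULL) {
  stopifnot(inherits(net, "ppi_network"), inherits(pathways, "pathway_collection"))
  if (is.null(net$degree_bin)) stop("degree bins not assigned; call assign_degree_bins()")
  seeds <- unique(as.character(seeds))
  in_net <- seeds %in% net$nodes
  if (any(!in_net)) {
    warning(sprintf("%d seed gene(s) not in the network dropped: %s",
                    sum(!in_net), paste(head(seeds[!in_net], 5), collapse = ", ")))
    seeds <- seeds[in_net]
  }
  sets <- pathways$sets
  empty <- data.table::data.table(
    seed = character(), pathway = character(), observed = numeric(),
    perm_count_ge = integer(), p_perm = numeric(), p_adj = numeric(),
    p_raw = numeric(), p_raw_adj = numeric(), significant = logical())
  if (length(seeds) == 0 || length(sets) == 0) return(empty)
  if (is.null(ppr_cache)) ppr_cache <- new.env(parent = emptyenv())

  M <- .pathway_matrix(net, sets)
  n_pw <- length(sets)
  ## pathway-mean profiles (one column per node index), filled lazily in
  ## batches: the PPR solve dominates, the M %*% S product is cheap
  profiles <- new.env(parent = emptyenv())
  ensure_profiles <- function(idxs) {
    todo <- idxs[vapply(as.character(idxs), function(k) is.null(profiles[[k]]),
                        logical(1))]
    if (length(todo)) {
      S <- vapply(todo, function(i) .ppr_cached(net, i, params, ppr_cache),
                  numeric(length(net$nodes)))
      P <- as.matrix(M %*% S)
      for (j in seq_along(todo)) profiles[[as.character(todo[j])]] <- P[, j]
    }
    invisible(NULL)
  }

  res <- vector("list", length(seeds))
  for (si in seq_along(seeds)) {
    s <- seeds[si]
    seed_idx <- match(s, net$nodes)
    ensure_profiles(seed_idx)
    obs_profile <- profiles[[as.character(seed_idx)]]
    pool <- .perm_pool(net, seed_idx)
    ## one independent substream per pathway so any evaluation order (or
    ## subset) reproduces identical counts
    draws_by_pw <- lapply(names(sets), function(pw) {
      .pd_with_seed(.pd_stream_seed(params$rng_seed, s, pw),
                    sample(pool, params$n_perm, replace = TRUE))
    })
    uniq <- unique(unlist(draws_by_pw, use.names = FALSE))
    ensure_profiles(uniq)
    PM <- vapply(uniq, function(i) profiles[[as.character(i)]],
                 numeric(n_pw))
    if (n_pw == 1) PM <- matrix(PM, nrow = 1)
    cnt <- vapply(seq_len(n_pw), function(pi) {
      sum(PM[pi, match(draws_by_pw[[pi]], uniq)] >= obs_profile[pi])
    }, numeric(1))
    res[[si]] <- data.table::data.table(
      seed = s, pathway = names(sets), observed = obs_profile,
      perm_count_ge = as.integer(cnt))
  }
  out <- data.table::rbindlist(res)
  out[, p_perm := (1 + perm_count_ge) / (1 + params$n_perm)]
  out[, p_adj := pmin(1, p_perm * m_family)]
  out[, p_raw := perm_count_ge / params$n_perm]
  out[, p_raw_adj := pmin(1, p_raw * m_family)]
  out[, significant := p_raw_adj < 0.05]
  out[]
}

#' Link shared genes to canonical pathways by network propagation
#'
#' For every (shared gene, pathway) pair, computes the observed mean PPR
#' score of the pathway from the seed and a degree-matched permutation
#' p-value, Bonferroni-adjusted for the number of seeds times the number
#' of pathways tested. A pair is flagged significant when the adjusted
#' frequency p-value `p_raw_adj` is below 0.05 (see [permutation_p()] for
#' the two estimators).
#'
#' @param net a `ppi_network` with degree bins.
#' @param seeds character vector of shared-gene Entrez IDs; seeds absent
#'   from the network are dropped with a warning.
#' @param pathways a network-restricted `pathway_collection`.
#' @param params a [ppr_params()].
#' @param ppr_cache optional environment for memoising PPR vectors across
#'   stages of a pipeline run.
#' @return data.table with one row per (seed, pathway): `seed`,
#'   `pathway`, `observed`, `perm_count_ge`, `p_perm`, `p_adj`, `p_raw`,
#'   `p_raw_adj`, `significant`.
#' @export
link_seeds_to_pathways <- function(net, seeds, pathways, params = ppr_params(),
                                   ppr_cache = NULL) {
  m <- length(unique(as.character(seeds))[unique(as.character(seeds)) %in% net$nodes]) *
    length(pathways$sets)
  .link_stage(net, seeds, pathways, params, m_family = max(1L, m),
              ppr_cache = ppr_cache)
}

#' Link drug targets to shared canonical pathways
#'
#' Identical propagation/permutation machinery as
#' [link_seeds_to_pathways()], run with drug targets as seeds against the
#' pathways found significant in the gene stage. The Bonferroni family is
#' the number of distinct targets tested for the predisposing disease
#' (the shared-pathway set is fixed by the first stage and is not counted
#' again); override with `family_size` when the tested family spans more
#' targets than this call.
#'
#' @inheritParams link_seeds_to_pathways
#' @param targets character vector of drug-target Entrez IDs.
#' @param family_size Bonferroni family size; default is the number of
#'   distinct in-network targets in this call.
#' @return LinkageResult data.table (see [link_seeds_to_pathways()]).
#' @export
link_targets_to_pathways <- function(net, targets, pathways,
                                     params = ppr_params(),
                                     family_size = NULL, ppr_cache = NULL) {
  targets <- unique(as.character(targets))
  m <- family_size %||% sum(targets %in% net$nodes)
  .link_stage(net, targets, pathways, params, m_family = max(1L, m),
              ppr_cache = ppr_cache)
}
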