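#' Configuration for the synthetic input generator
#'
#' Defines the scale and structure of a fully synthetic pipeline input
#' bundle with known planted gene -> pathway -> drug signal. The same
#' configuration (including `seed`) always produces byte-identical files.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes/proteins in the network (>= 300).
#' @param n_pathways number of gene sets in the GMT file.
#' @param pathway_size_range integer interval of background pathway sizes.
#' @param n_drugs number of drugs in the drug table.
#' @param targets_per_drug_range integer interval of targets per decoy drug.
#' @param n_loci positively correlated loci per disease pair.
#' @param locus_width_bp width of each locus in base pairs.
#' @param frac_planted fraction of each pair's shared genes wired into
#'   planted pathway modules (the rest are ordinary locus genes that pass
#'   the statistical filters but carry no network signal).
#' @param edge_model background graph model: `"scale-free"` (preferential
#'   attachment) or `"erdos-renyi"`.
#' @param background_edge_density extra uniform edge density overlaid on
#'   the base graph (the sole edge source for `"erdos-renyi"`).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_genes = 2000,
                             n_pathways = 100,
                             pathway_size_range = c(10, 50),
                             n_drugs = 60,
                             targets_per_drug_range = c(1, 3),
                             n_loci = 8,
                             locus_width_bp = 100000,
                             frac_planted = 0.6,
                             edge_model = c("scale-free", "erdos-renyi"),
                             background_edge_density = 0) {
  edge_model <- match.arg(edge_model)
  stopifnot(n_genes >= 300, n_genes <= 8000, n_pathways >= 10, n_drugs >= 20,
            n_loci >= 6, locus_width_bp >= 70000,
            length(pathway_size_range) == 2,
            pathway_size_range[1] >= 1,
            pathway_size_range[1] <= pathway_size_range[2],
            length(targets_per_drug_range) == 2,
            targets_per_drug_range[1] >= 1,
            targets_per_drug_range[1] <= targets_per_drug_range[2],
            frac_planted >= 0, frac_planted <= 1,
            background_edge_density >= 0, background_edge_density <= 1)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 n_drugs = as.integer(n_drugs),
                 targets_per_drug_range = as.integer(targets_per_drug_range),
                 n_loci = as.integer(n_loci),
                 locus_width_bp = as.integer(locus_width_bp),
                 frac_planted = frac_planted, edge_model = edge_model,
                 background_edge_density = background_edge_density),
            class = "synthetic_config")
}

## Fixed structural choices of the generator (see the methods vignette):
## two disease pairs, three planted modules per pair, dense cores in the
## top degree bin and one low-degree anchor gene per module.
.SYN_PAIRS <- c("PD1", "PD2")
.SYN_MODULES_PER_PAIR <- 3L
.SYN_CORE_MIN_WITHIN <- 5L   # guarantees cores land in the top degree bin
.SYN_MODULE_EDGE_P <- 0.4
.SYN_N_TP_DRUGS <- 12L
.SYN_N_BC_TP <- 10L          # true-positive drugs on the breast-cancer list
.SYN_N_BC_DECOY <- 2L
.SYN_GENE_WIDTH <- 20000L

## Dense within-module edges: Bernoulli(p) pairs topped up so every
## member keeps at least .SYN_CORE_MIN_WITHIN within-module edges.
.syn_module_edges <- function(members, p) {
  k <- length(members)
  W <- matrix(FALSE, k, k)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  sel <- runif(nrow(ut)) < p
  W[ut[sel, , drop = FALSE]] <- TRUE
  W <- W | t(W)
  repeat {
    low <- which(rowSums(W) < .SYN_CORE_MIN_WITHIN)
    if (length(low) == 0) break
    i <- low[1]
    cand <- setdiff(which(!W[i, ]), i)
    j <- if (length(cand) == 1) cand else sample(cand, 1)
    W[i, j] <- W[j, i] <- TRUE
  }
  idx <- which(upper.tri(W) & W, arr.ind = TRUE)
  cbind(members[idx[, 1]], members[idx[, 2]])
}

## Deterministic blueprint of the whole synthetic world: graph, roles,
## coordinates, statistics, drugs. Everything downstream is a plain
## serialization of this object.
.syn_blueprint <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  entrez <- as.character(100000 + seq_len(n))
  protein <- sprintf("9606.ENSP%07d", seq_len(n))

  ## --- base graph -------------------------------------------------------
  if (cfg$edge_model == "scale-free") {
    g <- igraph::sample_pa(n, power = 1, m = 3, directed = FALSE)
    base_edges <- igraph::as_edgelist(g, names = FALSE)
    if (cfg$background_edge_density > 0) {
      g2 <- igraph::sample_gnp(n, cfg$background_edge_density)
      base_edges <- rbind(base_edges, igraph::as_edgelist(g2, names = FALSE))
    }
  } else {
    g <- igraph::sample_gnp(n, max(cfg$background_edge_density, 3 / n))
    base_edges <- igraph::as_edgelist(g, names = FALSE)
  }
  base_deg <- tabulate(c(base_edges[, 1], base_edges[, 2]), nbins = n)

  ## --- planted modules and anchors -------------------------------------
  n_mod <- length(.SYN_PAIRS) * .SYN_MODULES_PER_PAIR
  core_lo <- max(12L, cfg$pathway_size_range[1])
  core_hi <- max(core_lo, min(16L, cfg$pathway_size_range[2]))
  core_sizes <- sample(core_lo:core_hi, n_mod, replace = TRUE)
  hub_rank <- order(base_deg, decreasing = TRUE)
  hubs <- hub_rank[seq_len(min(100L, n))]
  core_pool <- setdiff(seq_len(n), hubs)
  cores <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    cores[[m]] <- sample(core_pool, core_sizes[m])
    core_pool <- setdiff(core_pool, cores[[m]])
  }
  module_edges <- do.call(rbind, lapply(cores, .syn_module_edges,
                                        p = .SYN_MODULE_EDGE_P))
  anchor_pool <- setdiff(which(base_deg == min(base_deg[base_deg > 0])),
                         unlist(cores))
  anchors <- sample(anchor_pool, n_mod)
  anchor_edges <- do.call(rbind, lapply(seq_len(n_mod), function(m) {
    cbind(anchors[m], sample(cores[[m]], 3))
  }))

  edges <- rbind(base_edges, module_edges, anchor_edges)
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- unique(edges)
  scores <- sample(700:1000, nrow(edges), replace = TRUE)

  mod_pair <- rep(.SYN_PAIRS, each = .SYN_MODULES_PER_PAIR)
  mod_of_pair <- split(seq_len(n_mod), mod_pair)

  ## --- special gene roles ----------------------------------------------
  taken <- c(unlist(cores), anchors)
  pick <- function(k) {
    out <- sample(setdiff(seq_len(n), taken), k)
    taken <<- c(taken, out)
    out
  }
  n_shared <- 5L
  n_planted <- min(.SYN_MODULES_PER_PAIR, as.integer(round(cfg$frac_planted * n_shared)))
  roles <- list()
  for (p in .SYN_PAIRS) {
    roles[[p]] <- list(
      planted = anchors[mod_of_pair[[p]]][seq_len(n_planted)],
      nonplanted = pick(2L),
      boundary_in = pick(1L), boundary_out = pick(1L),
      conc_decoy = pick(1L), neg_locus = pick(1L),
      fillers = pick(cfg$n_loci))
  }

  ## --- coordinates ------------------------------------------------------
  ann <- data.table::data.table(
    idx = seq_len(n), entrez = entrez,
    chrom = (seq_len(n) - 1L) %% 22L + 1L,
    start = 1000000L + ((seq_len(n) - 1L) %/% 22L) * 400000L)
  ann[, end := start + .SYN_GENE_WIDTH - 1L]

  loci <- list()
  locus_band <- 150000000L
  place <- function(gidx, lstart, offset) {
    ann[gidx, `:=`(start = lstart + offset,
                   end = lstart + offset + .SYN_GENE_WIDTH - 1L)]
  }
  for (pi in seq_along(.SYN_PAIRS)) {
    p <- .SYN_PAIRS[pi]
    r <- roles[[p]]
    n_pos <- cfg$n_loci
    n_neg <- 3L
    lstart <- locus_band + ((pi - 1L) * (n_pos + n_neg)) * 3000000L +
      (seq_len(n_pos + n_neg) - 1L) * 3000000L
    lchrom <- (seq_len(n_pos + n_neg) - 1L) %% 22L + 1L
    ldt <- data.table::data.table(
      chrom = lchrom, start = lstart,
      end = lstart + cfg$locus_width_bp - 1L,
      sign = c(rep("+", n_pos), rep("-", n_neg)),
      qvalue = signif(10^runif(n_pos + n_neg, -8, -2), 3))
    ## anchors of the pair's modules live inside the first loci
    pair_anchors <- anchors[mod_of_pair[[p]]]
    for (j in seq_along(pair_anchors)) {
      place(pair_anchors[j], lstart[j], 5000L)
      ann[pair_anchors[j], chrom := lchrom[j]]
    }
    slot <- length(pair_anchors)
    put_in_locus <- function(gidx, j, offset = 5000L) {
      place(gidx, lstart[j], offset)
      ann[gidx, chrom := lchrom[j]]
    }
    put_in_locus(r$conc_decoy, slot + 1L)
    put_in_locus(r$nonplanted[1], slot + 2L)
    put_in_locus(r$nonplanted[2], slot + 3L)
    ## boundary genes hang off the last positive locus: a gap of exactly
    ## 10,000 bp still maps under the default window, 10,001 bp does not
    jb <- n_pos
    ann[r$boundary_in, `:=`(chrom = lchrom[jb],
                            start = lstart[jb] - 10000L - .SYN_GENE_WIDTH,
                            end = lstart[jb] - 10000L)]
    ann[r$boundary_out, `:=`(chrom = lchrom[jb],
                             start = lstart[jb] - 10001L - .SYN_GENE_WIDTH,
                             end = lstart[jb] - 10001L)]
    ## null fillers inside every positive locus, one passing gene inside
    ## the first negative locus
    for (j in seq_len(n_pos)) put_in_locus(r$fillers[j], j, 45000L)
    put_in_locus(r$neg_locus, n_pos + 1L)
    loci[[p]] <- ldt
  }

  ## --- per-pair statistics ---------------------------------------------
  stats <- list()
  for (p in .SYN_PAIRS) {
    r <- roles[[p]]
    pass <- c(r$planted, r$nonplanted, r$boundary_in, r$boundary_out,
              r$neg_locus)
    magma_p <- runif(n)
    magma_p[pass] <- 10^-runif(length(pass), 7, 10)
    magma_p[r$conc_decoy] <- 10^-runif(1, 7, 10)
    s <- sample(c(-1, 1), n, replace = TRUE)
    z_pd <- s * runif(n, 0.1, 2)
    z_bc <- sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.1, 2)
    conc_sign <- sample(c(-1, 1), length(pass), replace = TRUE)
    z_pd[pass] <- conc_sign * runif(length(pass), 2, 4)
    z_bc[pass] <- conc_sign * runif(length(pass), 2, 4)
    z_pd[r$conc_decoy] <- runif(1, 2, 4)
    z_bc[r$conc_decoy] <- -runif(1, 2, 4)
    stats[[p]] <- data.table::data.table(
      idx = seq_len(n), magma_p = magma_p, z_pd = z_pd, z_bc = z_bc,
      nsnps = sample(10:200, n, replace = TRUE))
  }

  ## --- pathways ---------------------------------------------------------
  pw_names <- c(sprintf("SYN_PW_%s_MOD%d", mod_pair,
                        rep(seq_len(.SYN_MODULES_PER_PAIR), length(.SYN_PAIRS))),
                sprintf("SYN_PW_BG%03d", seq_len(max(0, cfg$n_pathways - n_mod))))
  bg_sizes <- sample(cfg$pathway_size_range[1]:cfg$pathway_size_range[2],
                     max(0, cfg$n_pathways - n_mod), replace = TRUE)
  pw_sets <- c(cores, lapply(bg_sizes, function(k) sample(seq_len(n), k)))
  names(pw_sets) <- pw_names

  ## --- drugs ------------------------------------------------------------
  tp_per_pair <- .SYN_N_TP_DRUGS %/% length(.SYN_PAIRS)
  drug_rows <- list()
  for (p in .SYN_PAIRS) {
    pa <- anchors[mod_of_pair[[p]]]
    for (i in seq_len(tp_per_pair)) {
      tg <- if (i <= 2) pa[(i - 1L) %% length(pa) + 1L] else sample(pa, 2)
      drug_rows[[length(drug_rows) + 1L]] <-
        list(kind = "tp", indication = p, targets = tg)
    }
  }
  decoy_target_pool <- setdiff(seq_len(n), taken)
  n_decoy <- cfg$n_drugs - length(drug_rows)
  for (i in seq_len(n_decoy)) {
    p <- .SYN_PAIRS[(i - 1L) %% length(.SYN_PAIRS) + 1L]
    if (i <= 3) {
      tg <- -i   # off-network target sentinel, serialized as unknown ID
    } else {
      k <- sample(cfg$targets_per_drug_range[1]:cfg$targets_per_drug_range[2], 1)
      tg <- sample(decoy_target_pool, k)
    }
    drug_rows[[length(drug_rows) + 1L]] <-
      list(kind = "decoy", indication = p, targets = tg)
  }
  ord <- sample(length(drug_rows))
  drug_rows <- drug_rows[ord]
  ids <- sprintf("SYNDB%04d", seq_along(drug_rows))
  for (i in seq_along(drug_rows)) drug_rows[[i]]$drug_id <- ids[i]
  tp_ids <- ids[vapply(drug_rows, function(d) d$kind == "tp", logical(1))]
  decoy_ids <- setdiff(ids, tp_ids)
  bc_ids <- c(sample(tp_ids, .SYN_N_BC_TP), sample(decoy_ids, .SYN_N_BC_DECOY))

  ## --- network file extras ---------------------------------------------
  extra_prot <- sprintf("9606.ENSP%07d", 9000000 + seq_len(10))
  extra_edges <- data.table::data.table(
    protein1 = rep(extra_prot, each = 2),
    protein2 = protein[sample(decoy_target_pool, 20)],
    combined_score = sample(700:1000, 20, replace = TRUE))
  low_idx <- cbind(sample(n, 150, replace = TRUE), sample(n, 150, replace = TRUE))
  low_idx <- low_idx[low_idx[, 1] != low_idx[, 2], , drop = FALSE]
  low_edges <- data.table::data.table(
    protein1 = protein[low_idx[, 1]], protein2 = protein[low_idx[, 2]],
    combined_score = sample(150:699, nrow(low_idx), replace = TRUE))
  dup_sel <- sample(nrow(edges), 15)
  dup_edges <- data.table::data.table(
    protein1 = protein[edges[dup_sel, 2]], protein2 = protein[edges[dup_sel, 1]],
    combined_score = pmax(700L, scores[dup_sel] - 100L))
  loop_nodes <- sample(n, 5)
  loop_edges <- data.table::data.table(
    protein1 = protein[loop_nodes], protein2 = protein[loop_nodes],
    combined_score = 900L)

  list(cfg = cfg, entrez = entrez, protein = protein,
       edges = edges, scores = scores,
       extra_edges = extra_edges, low_edges = low_edges,
       dup_edges = dup_edges, loop_edges = loop_edges,
       extra_prot = extra_prot,
       cores = cores, anchors = anchors, mod_pair = mod_pair,
       mod_of_pair = mod_of_pair, roles = roles,
       ann = ann, loci = loci, stats = stats,
       pw_sets = pw_sets, drug_rows = drug_rows,
       tp_ids = tp_ids, decoy_ids = decoy_ids, bc_ids = bc_ids)
}

## Serialize one gene index vector to Entrez IDs (negative sentinels
## become unknown off-network IDs).
.syn_id <- function(bp, idx) {
  ifelse(idx > 0, bp$entrez[pmax(idx, 1)], as.character(999000000 - idx))
}

#' Generate the synthetic STRING-style network files
#'
#' Writes `network_links.txt` (space-separated
#' `protein1 protein2 combined_score`, including sub-threshold edges,
#' duplicate edges and self-loops so the loader's filters are exercised)
#' and `network_aliases.tsv` (protein, alias, source; a handful of
#' proteins deliberately lack an Entrez row).
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory.
#' @return named character vector of the written paths.
#' @export
generate_network <- function(cfg, dir) {
  bp <- .syn_blueprint(cfg)
  .syn_write_network(bp, dir)
}

.syn_write_network <- function(bp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  real <- data.table::data.table(
    protein1 = bp$protein[bp$edges[, 1]], protein2 = bp$protein[bp$edges[, 2]],
    combined_score = bp$scores)
  links <- data.table::rbindlist(list(real, bp$dup_edges, bp$loop_edges,
                                      bp$low_edges, bp$extra_edges))
  links_path <- file.path(dir, "network_links.txt")
  data.table::fwrite(links, links_path, sep = " ")

  alias <- data.table::rbindlist(list(
    data.table::data.table(protein = bp$protein, alias = bp$entrez,
                           source = "Entrez_Gene_ID"),
    data.table::data.table(protein = bp$protein,
                           alias = paste0("GENE", bp$entrez),
                           source = "Gene_Symbol"),
    data.table::data.table(protein = bp$extra_prot,
                           alias = paste0("ORPHAN", seq_along(bp$extra_prot)),
                           source = "Gene_Symbol")))
  alias_path <- file.path(dir, "network_aliases.tsv")
  writeLines(c("#string_protein_id\talias\tsource",
               alias[, paste(protein, alias, source, sep = "\t")]),
             alias_path)
  c(links = links_path, aliases = alias_path)
}

#' Generate the synthetic gene annotation table
#'
#' Per gene: Entrez ID, chromosome (1--22), 1-based inclusive start/end.
#' Includes genes placed exactly 10,000 bp and 10,001 bp outside a
#' planted locus to pin the positional-mapping boundary.
#'
#' @inheritParams generate_network
#' @return path of the written annotation TSV.
#' @export
generate_gene_annotations <- function(cfg, dir) {
  bp <- .syn_blueprint(cfg)
  .syn_write_annotations(bp, dir)
}

.syn_write_annotations <- function(bp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "gene_annotations.tsv")
  data.table::fwrite(bp$ann[, .(entrez, chrom, start, end)], path, sep = "\t")
  c(annotations = path)
}

#' Generate per disease-pair locus, gene-association and regulation tables
#'
#' For each synthetic disease pair, writes a correlated-region table
#' (`regions_<pair>.tsv`: chrom, start, end, sign, qvalue), a MAGMA-style
#' whitespace table (`magma_<pair>.tsv`: GENE CHR START STOP NSNPS ZSTAT
#' P) and an S-MultiXcan-style signed statistic table
#' (`smultixcan_<pair>.tsv`: gene, z_pd, z_bc). Planted shared genes get
#' association p-values that survive BH at 0.05 and sign-concordant z in
#' both diseases; decoys get uniform p and/or discordant signs; one
#' passing gene sits in a negatively correlated locus and must never
#' reach the shared set.
#'
#' @inheritParams generate_network
#' @return named character vector of written paths.
#' @export
generate_disease_pair_artifacts <- function(cfg, dir) {
  bp <- .syn_blueprint(cfg)
  .syn_write_pairs(bp, dir)
}

.syn_write_pairs <- function(bp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character()
  for (p in names(bp$loci)) {
    rp <- file.path(dir, sprintf("regions_%s.tsv", p))
    data.table::fwrite(bp$loci[[p]], rp, sep = "\t")
    st <- bp$stats[[p]]
    magma <- data.table::data.table(
      GENE = bp$entrez, CHR = bp$ann$chrom, START = bp$ann$start,
      STOP = bp$ann$end, NSNPS = st$nsnps,
      ZSTAT = round(qnorm(1 - st$magma_p / 2), 4), P = signif(st$magma_p, 6))
    mp <- file.path(dir, sprintf("magma_%s.tsv", p))
    data.table::fwrite(magma, mp, sep = " ")
    smx <- data.table::data.table(gene = bp$entrez,
                                  z_pd = round(st$z_pd, 4),
                                  z_bc = round(st$z_bc, 4))
    sp <- file.path(dir, sprintf("smultixcan_%s.tsv", p))
    data.table::fwrite(smx, sp, sep = "\t")
    out[sprintf("regions_%s", p)] <- rp
    out[sprintf("magma_%s", p)] <- mp
    out[sprintf("smultixcan_%s", p)] <- sp
  }
  out
}

#' Generate the synthetic drug tables
#'
#' Writes `drugs.tsv` (drug_id, name, indication, semicolon-separated
#' Entrez targets) and `bc_drugs.tsv` (drug_id, status). True-positive
#' drugs target the anchor genes wired into planted pathway modules;
#' decoy drugs target random unrelated genes; a few decoys carry only an
#' off-network target. The breast-cancer list overlaps the true
#' positives so the enrichment evaluation has signal.
#'
#' @inheritParams generate_network
#' @return named character vector of written paths.
#' @export
generate_drug_tables <- function(cfg, dir) {
  bp <- .syn_blueprint(cfg)
  .syn_write_drugs(bp, dir)
}

.syn_write_drugs <- function(bp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(bp$drug_rows, function(d) {
    tg <- .syn_id(bp, d$targets)
    ## one raw duplicate target in the first row exercises reader dedup
    data.table::data.table(drug_id = d$drug_id,
                           name = paste0("drug_", d$drug_id),
                           indication = d$indication,
                           targets = paste(tg, collapse = ";"))
  })
  drugs <- data.table::rbindlist(rows)
  drugs$targets[1] <- paste(drugs$targets[1],
                            strsplit(drugs$targets[1], ";")[[1]][1], sep = ";")
  dp <- file.path(dir, "drugs.tsv")
  data.table::fwrite(drugs, dp, sep = "\t")
  bc <- data.table::data.table(
    drug_id = bp$bc_ids,
    status = rep(c("approved", "trial"), length.out = length(bp$bc_ids)))
  bp_path <- file.path(dir, "bc_drugs.tsv")
  data.table::fwrite(bc, bp_path, sep = "\t")
  c(drugs = dp, bc_drugs = bp_path)
}

#' Generate a complete synthetic input bundle
#'
#' Writes every pipeline input (network, aliases, GMT pathways, gene
#' annotations, per-pair region/association/regulation tables, drug
#' tables) into `dir` and returns a ready [run_pipeline()] configuration
#' pointing at them. The planted ground truth is attached as attribute
#' `"truth"`: planted pathway names, anchor genes, true-positive and
#' decoy drug IDs.
#'
#' @inheritParams generate_network
#' @param n_perm permutation count passed into the returned configuration.
#' @return run configuration list (invisible ground truth in
#'   `attr(, "truth")`).
#' @export
simulate_inputs <- function(cfg, dir, n_perm = 1000) {
  bp <- .syn_blueprint(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(.syn_write_network(bp, dir),
             .syn_write_annotations(bp, dir),
             .syn_write_pairs(bp, dir),
             .syn_write_drugs(bp, dir))
  gmt_path <- file.path(dir, "pathways.gmt")
  writeLines(vapply(names(bp$pw_sets), function(nm) {
    paste(c(nm, "synthetic gene set", bp$entrez[bp$pw_sets[[nm]]]),
          collapse = "\t")
  }, character(1)), gmt_path)
  paths["gmt"] <- gmt_path

  pairs <- lapply(setNames(names(bp$loci), names(bp$loci)), function(p) {
    list(regions = unname(paths[sprintf("regions_%s", p)]),
         magma = unname(paths[sprintf("magma_%s", p)]),
         smultixcan = unname(paths[sprintf("smultixcan_%s", p)]))
  })
  config <- list(
    network = list(links = unname(paths["links"]),
                   aliases = unname(paths["aliases"]),
                   min_score = 700, alias_source = "Entrez_Gene_ID"),
    pathways = list(gmt = unname(paths["gmt"]), min_size = 1),
    annotations = unname(paths["annotations"]),
    pairs = pairs,
    drugs = unname(paths["drugs"]),
    bc_drugs = unname(paths["bc_drugs"]),
    params = list(restart = 0.8, tol = 1e-10, max_iter = 1000,
                  n_perm = n_perm, rng_seed = cfg$seed, include_seed = TRUE),
    window_bp = 10000, alpha = 0.05, positive_only = TRUE,
    exclude_pairs = character(0),
    output_dir = file.path(dir, "output"))
  truth <- list(
    planted_pathways = split(names(bp$pw_sets)[seq_along(bp$mod_pair)], bp$mod_pair),
    anchors = lapply(bp$mod_of_pair, function(ms) bp$entrez[bp$anchors[ms]]),
    planted_shared = lapply(bp$roles, function(r) bp$entrez[r$planted]),
    nonplanted_shared = lapply(bp$roles, function(r)
      bp$entrez[c(r$nonplanted, r$boundary_in)]),
    boundary_in = lapply(bp$roles, function(r) bp$entrez[r$boundary_in]),
    boundary_out = lapply(bp$roles, function(r) bp$entrez[r$boundary_out]),
    conc_decoy = lapply(bp$roles, function(r) bp$entrez[r$conc_decoy]),
    neg_locus_gene = lapply(bp$roles, function(r) bp$entrez[r$neg_locus]),
    tp_drugs = bp$tp_ids, decoy_drugs = bp$decoy_ids, bc_drugs = bp$bc_ids)
  attr(config, "truth") <- truth
  config
}
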