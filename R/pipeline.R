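#' Run the full shared-genetics drug-repurposing pipeline
#'
#' Config-driven orchestration of every stage: network loading and degree
#' binning; pathway restriction; per disease-pair shared-gene extraction
#' (positional mapping of positively correlated loci, gene-association BH
#' filter, sign-concordance filter); gene-stage PPR linkage of shared
#' genes to pathways; drug-stage PPR linkage of the indicated drugs'
#' targets to the shared pathways; candidate assembly with evidence
#' chains; and the one-sided Fisher enrichment against the external drug
#' list. Personalized-PageRank vectors are cached across stages (a target
#' shared by two drugs is propagated once). Deterministic under a fixed
#' configuration.
#'
#' @param config either a configuration list (as returned by
#'   [simulate_inputs()]) or the path to a YAML file with the same
#'   structure: `network` (links/aliases/min_score/alias_source),
#'   `pathways` (gmt/min_size), `annotations`, `pairs` (named list with
#'   regions/magma/smultixcan paths per disease pair), `drugs`,
#'   `bc_drugs`, `params` (restart/tol/max_iter/n_perm/rng_seed/
#'   include_seed), `window_bp`, `alpha`, `positive_only`,
#'   `exclude_pairs`, `output_dir`.
#' @param write_output write the report bundle to `config$output_dir`
#'   (default TRUE when an output directory is configured).
#' @return list of class `pleiodrug_run`: `network`, `pathways`,
#'   `shared_genes` (per pair), `gene_linkage`, `shared_pathways` (per
#'   pair), `target_linkage`, `candidates`, `chains`, `enrichment`,
#'   `drugs`, `config`, `timings`.
#' @export
run_pipeline <- function(config, write_output = !is.null(config$output_dir)) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- t1 - t0
    t0 <<- t1
    .pd_msg("stage %-16s %6.1fs", stage, timings[stage])
  }

  inputs <- c(config$network$links, config$network$aliases,
              config$pathways$gmt, config$annotations, config$drugs,
              config$bc_drugs,
              unlist(lapply(config$pairs, function(p)
                c(p$regions, p$magma, p$smultixcan))))
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    stop("input file(s) not found: ", paste(missing_in, collapse = ", "))
  }

  pr <- config$params %||% list()
  params <- ppr_params(restart = pr$restart %||% 0.8,
                       tol = pr$tol %||% 1e-10,
                       max_iter = pr$max_iter %||% 1000,
                       n_perm = pr$n_perm %||% 1000,
                       rng_seed = pr$rng_seed %||% 1,
                       include_seed = pr$include_seed %||% TRUE)
  alpha <- config$alpha %||% 0.05
  window_bp <- config$window_bp %||% 10000
  positive_only <- config$positive_only %||% TRUE

  net <- load_string_network(config$network$links, config$network$aliases,
                             min_score = config$network$min_score %||% 700,
                             alias_source = config$network$alias_source %||%
                               "Entrez_Gene_ID")
  net <- assign_degree_bins(net)
  tick("network")

  pw <- restrict_to_network(read_gmt(config$pathways$gmt), net,
                            min_size = config$pathways$min_size %||% 1)
  ann <- read_gene_annotations(config$annotations)
  tick("pathways")

  pairs <- config$pairs
  excl <- config$exclude_pairs %||% character(0)
  pairs <- pairs[!(names(pairs) %in% excl)]
  if (length(pairs) == 0) stop("no disease pairs left after exclusions")

  ppr_cache <- new.env(parent = emptyenv())
  shared_genes <- list()
  gene_linkage <- list()
  shared_pw <- list()
  target_linkage <- list()
  drugs <- read_drug_table(config$drugs)
  bc <- read_bc_drugs(config$bc_drugs)

  for (p in names(pairs)) {
    pc <- pairs[[p]]
    regions <- read_regions(pc$regions)
    cand <- map_regions_to_genes(regions, ann, window_bp = window_bp,
                                 positive_only = positive_only)
    magma <- read_magma(pc$magma)
    smx <- read_smultixcan(pc$smultixcan)
    gs <- merge(magma, smx, by = "entrez", all = TRUE)
    sgs <- filter_shared_genes(cand, gs, alpha = alpha, disease_pair = p)
    shared_genes[[p]] <- sgs
    .pd_msg("pair %s: %d locus gene(s), %d shared gene(s)",
            p, nrow(cand), length(sgs$genes))

    gl <- link_seeds_to_pathways(net, sgs$genes, pw, params,
                                 ppr_cache = ppr_cache)
    gl[, disease_pair := p]
    gene_linkage[[p]] <- gl
    sp <- shared_pathways(gl, pw)
    shared_pw[[p]] <- sp

    pair_drugs <- drugs[indication == p]
    targets <- unique(unlist(pair_drugs$targets))
    targets_in <- targets[targets %in% net$nodes]
    if (length(sp$sets) > 0 && length(targets_in) > 0) {
      sub_pw <- structure(list(sets = sp$sets,
                               description = setNames(rep("", length(sp$sets)),
                                                      names(sp$sets))),
                          class = "pathway_collection")
      tl <- link_targets_to_pathways(net, targets_in, sub_pw, params,
                                     family_size = length(targets_in),
                                     ppr_cache = ppr_cache)
      tl[, disease_pair := p]
      target_linkage[[p]] <- tl
    }
  }
  tick("linkage")

  gene_linkage <- data.table::rbindlist(gene_linkage, use.names = TRUE)
  target_linkage <- if (length(target_linkage)) {
    data.table::rbindlist(target_linkage, use.names = TRUE)
  } else {
    data.table::data.table(seed = character(), pathway = character(),
                           observed = numeric(), perm_count_ge = integer(),
                           p_perm = numeric(), p_adj = numeric(),
                           p_raw = numeric(), p_raw_adj = numeric(),
                           significant = logical(),
                           disease_pair = character())
  }

  cand_res <- candidate_drugs(drugs, target_linkage,
                              lapply(shared_pw, `[[`, "support"))
  enrich <- fisher_enrichment(cand_res$candidates, drugs$drug_id, bc$drug_id)
  tick("evaluation")

  out <- structure(list(network = net, pathways = pw,
                        shared_genes = shared_genes,
                        gene_linkage = gene_linkage,
                        shared_pathways = shared_pw,
                        target_linkage = target_linkage,
                        candidates = cand_res$candidates,
                        chains = cand_res$chains,
                        enrichment = enrich, drugs = drugs,
                        config = config, timings = timings),
                   class = "pleiodrug_run")
  if (isTRUE(write_output)) {
    write_report(config$output_dir, drugs, cand_res, enrich,
                 config = config, input_files = inputs)
    for (p in names(shared_genes)) {
      write_shared_genes(shared_genes[[p]],
                         file.path(config$output_dir,
                                   sprintf("shared_genes_%s.tsv", p)))
    }
    data.table::fwrite(gene_linkage,
                       file.path(config$output_dir, "gene_linkage.tsv"),
                       sep = "\t")
    data.table::fwrite(target_linkage,
                       file.path(config$output_dir, "target_linkage.tsv"),
                       sep = "\t")
  }
  out
}

#' @export
print.pleiodrug_run <- function(x, ...) {
  cat("<pleiodrug_run>\n")
  cat(sprintf("  pairs: %s\n", paste(names(x$shared_genes), collapse = ", ")))
  for (p in names(x$shared_genes)) {
    cat(sprintf("  %s: %d shared gene(s), %d shared pathway(s)\n", p,
                length(x$shared_genes[[p]]$genes),
                length(x$shared_pathways[[p]]$sets)))
  }
  cat(sprintf("  candidates: %d of %d drugs\n",
              length(x$candidates), nrow(x$drugs)))
  cat(sprintf("  enrichment: p = %.3g, OR(cmle) = %.3g\n",
              x$enrichment$p_one_sided, x$enrichment$or_cmle))
  invisible(x)
}
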