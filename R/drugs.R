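#' Read a drug--target table
#'
#' @param path TSV with columns `drug_id`, `name`, `indication`
#'   (predisposing-disease tag) and `targets` (semicolon-separated Entrez
#'   IDs; deduplicated per drug on read).
#' @return data.table with a list-column `targets`.
#' @export
read_drug_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = "targets"))
  req <- c("drug_id", "name", "indication", "targets")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("drug table missing column(s): ", paste(miss, collapse = ", "))
  dt[, targets := lapply(strsplit(as.character(targets), ";", fixed = TRUE),
                         function(x) unique(x[nzchar(x)]))]
  dt[]
}

#' Read a target-disease drug list (investigated or approved)
#'
#' @param path TSV with columns `drug_id` and `status`
#'   (`trial`/`approved`).
#' @return data.table.
#' @export
read_bc_drugs <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!"drug_id" %in% names(dt)) stop("breast-cancer drug list needs a drug_id column")
  unique(dt, by = "drug_id")[]
}

#' Extract the shared canonical pathways from a gene-stage linkage table
#'
#' A pathway is "shared" for a disease pair when at least one shared gene
#' is significantly linked to it; each retained pathway is annotated with
#' its supporting shared genes.
#'
#' @param linkage gene-stage LinkageResult table from
#'   [link_seeds_to_pathways()].
#' @param pathways the `pathway_collection` the linkage was run against.
#' @return list of class `shared_pathway_set`: `sets` (named member
#'   lists), `support` (named list mapping pathway -> supporting shared
#'   genes), `table` (the significant rows).
#' @export
shared_pathways <- function(linkage, pathways) {
  stopifnot(inherits(pathways, "pathway_collection"))
  sig <- linkage[significant == TRUE]
  nm <- unique(sig$pathway)
  support <- lapply(setNames(nm, nm), function(p) unique(sig$seed[sig$pathway == p]))
  structure(list(sets = pathways$sets[nm], support = support, table = sig[]),
            class = "shared_pathway_set")
}

#' @export
print.shared_pathway_set <- function(x, ...) {
  cat(sprintf("<shared_pathway_set> %d pathway(s) supported by %d shared gene(s)\n",
              length(x$sets), length(unique(unlist(x$support)))))
  invisible(x)
}

#' Identify candidate drugs and their evidence chains
#'
#' A drug is a candidate for repurposing when at least one of its targets
#' is significantly linked to at least one shared canonical pathway of
#' its indication's disease pair (a drug indicated for several
#' predisposing diseases qualifies through any of them). Each significant
#' (drug, target, pathway) triple becomes an evidence chain annotated
#' with the shared genes supporting that pathway. Drugs with no
#' network-mapped targets can never be candidates but remain in the
#' evaluation universe.
#'
#' @param drugs data.table from [read_drug_table()].
#' @param target_linkage target-stage LinkageResult table carrying a
#'   `disease_pair` column (rbind of per-pair [link_targets_to_pathways()]
#'   results).
#' @param shared_support named list: `disease_pair` -> (named list:
#'   pathway -> supporting shared genes), i.e. the `support` fields of the
#'   per-pair [shared_pathways()] results.
#' @return list with `candidates` (character drug IDs), `chains`
#'   (data.table: `drug_id`, `disease_pair`, `target`, `pathway`,
#'   `shared_genes`, `p_raw_adj`), ordered by (drug, adjusted p).
#' @export
candidate_drugs <- function(drugs, target_linkage, shared_support) {
  sig <- target_linkage[significant == TRUE]
  chains <- data.table::data.table(
    drug_id = character(), disease_pair = character(), target = character(),
    pathway = character(), shared_genes = character(), p_raw_adj = numeric())
  if (nrow(sig)) {
    rows <- vector("list", nrow(drugs))
    for (i in seq_len(nrow(drugs))) {
      pair <- drugs$indication[i]
      hit <- sig[disease_pair == pair & seed %in% drugs$targets[[i]]]
      if (nrow(hit) == 0) next
      supp <- shared_support[[pair]]
      rows[[i]] <- data.table::data.table(
        drug_id = drugs$drug_id[i], disease_pair = pair,
        target = hit$seed, pathway = hit$pathway,
        shared_genes = vapply(hit$pathway, function(p)
          paste(sort(supp[[p]]), collapse = ";"), character(1)),
        p_raw_adj = hit$p_raw_adj)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) chains <- data.table::rbindlist(rows)
  }
  data.table::setorder(chains, drug_id, p_raw_adj, target, pathway)
  list(candidates = unique(chains$drug_id), chains = chains[])
}

## Conditional-MLE odds ratio of a 2x2 table: the psi maximizing Fisher's
## noncentral hypergeometric likelihood given the margins, found by
## solving E_psi[X] = a (the likelihood is log-concave with monotone
## conditional mean). Returns Inf/0 when a sits at the support boundary.
.or_cmle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  if (lo == hi) return(NaN)
  if (a >= hi) return(Inf)
  if (a <= lo) return(0)
  supp <- lo:hi
  lw <- lchoose(m, supp) + lchoose(n, k - supp)
  f <- function(lpsi) {
    w <- lw + supp * lpsi
    w <- exp(w - max(w))
    sum(supp * w) / sum(w) - a
  }
  exp(uniroot(f, c(-100, 100), tol = 1e-12)$root)
}

## Upper-tail one-sided exact p: P(X >= a) for X hypergeometric with the
## table's margins.
.fisher_upper_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  hi <- min(k, m)
  if (a > hi) return(1)
  sum(dhyper(a:hi, m, n, k))
}

#' One-sided Fisher enrichment of candidate drugs in an external list
#'
#' Builds the 2x2 table (candidate vs not, in the external drug list vs
#' not) over the full drug universe and reports the one-sided exact
#' p-value (upper hypergeometric tail), the conditional-MLE odds ratio
#' (the estimate standard Fisher-test implementations report) and the
#' sample cross-product odds ratio `ad/bc` (infinite when `bc = 0`).
#'
#' @param candidates character vector of candidate drug IDs.
#' @param universe character vector of all drugs indicated for the
#'   predisposing diseases (candidates must be a subset).
#' @param bc_drugs character vector of drugs investigated or approved for
#'   the target disease; matched to the universe by ID.
#' @return list of class `enrichment_result` with `table` (2x2 integer
#'   matrix), `p_one_sided`, `or_cmle`, `or_sample`.
#' @export
fisher_enrichment <- function(candidates, universe, bc_drugs) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty drug universe")
  candidates <- unique(as.character(candidates))
  if (!all(candidates %in% universe)) stop("candidates must be a subset of the universe")
  bc <- intersect(unique(as.character(bc_drugs)), universe)
  a <- length(intersect(candidates, bc))
  b <- length(setdiff(candidates, bc))
  c_ <- length(setdiff(bc, candidates))
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, c_, b, d), nrow = 2,
                dimnames = list(candidate = c("yes", "no"),
                                bc_drug = c("yes", "no")))
  or_sample <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  structure(list(table = tab,
                 p_one_sided = .fisher_upper_p(a, b, c_, d),
                 or_cmle = .or_cmle(a, b, c_, d),
                 or_sample = or_sample),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  print(x$table)
  cat(sprintf("one-sided exact p = %.3g; OR (conditional MLE) = %.3g; OR (sample) = %.3g\n",
              x$p_one_sided, x$or_cmle, x$or_sample))
  invisible(x)
}

#' Write the pipeline output bundle
#'
#' Writes `candidates.tsv` (drug, indication, number of evidence chains),
#' `chains.tsv` (drug -> target -> pathway -> shared genes, sorted by
#' drug and adjusted p), `enrichment.json`, and `run_metadata.json`
#' (configuration hash, RNG seed, input-file MD5 digests), so that two
#' runs under the same configuration produce identical digests.
#'
#' @param dir output directory (created if needed).
#' @param drugs drug table ([read_drug_table()]).
#' @param result list from [candidate_drugs()].
#' @param enrichment an `enrichment_result`.
#' @param config the run configuration list (hashed into the metadata).
#' @param input_files character vector of input paths to digest.
#' @return invisibly, the output directory.
#' @export
write_report <- function(dir, drugs, result, enrichment, config = list(),
                         input_files = character()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  cand <- data.table::data.table(drug_id = result$candidates)
  cand[, indication := drugs$indication[match(drug_id, drugs$drug_id)]]
  cand[, n_chains := vapply(drug_id, function(d) sum(result$chains$drug_id == d),
                            integer(1))]
  data.table::fwrite(cand, file.path(dir, "candidates.tsv"), sep = "\t")
  data.table::fwrite(result$chains, file.path(dir, "chains.tsv"), sep = "\t")
  jsonlite::write_json(
    list(table = unclass(enrichment$table),
         p_one_sided = enrichment$p_one_sided,
         or_cmle = enrichment$or_cmle,
         or_sample = enrichment$or_sample),
    file.path(dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)
  digests <- if (length(input_files)) as.list(tools::md5sum(input_files)) else list()
  jsonlite::write_json(
    list(config_hash = .pd_hash_string(
           jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)),
         rng_seed = config$params$rng_seed %||% NA,
         input_digests = digests),
    file.path(dir, "run_metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
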