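#' Quality-control and harmonize GWAS summary statistics
#'
#' Applies the standard pre-analysis filters to a summary-statistics table:
#' keep only bi-allelic SNPs (single-base A/C/G/T alleles, effect != alt)
#' on autosomal chromosomes 1--22 that match a unique rsID; when an `info`
#' column is present, drop records with imputation score below
#' `info_threshold` (the filter is applied only when the column exists,
#' since most GWAS do not report one). Alleles are then harmonized against
#' a reference panel table: a record whose effect allele equals the
#' reference ALT is kept as-is; one whose effect allele equals the
#' reference REF has its beta sign flipped and alleles swapped; records
#' matching neither orientation (or absent from the reference) are dropped.
#'
#' The operation is idempotent: re-applying it to its own output changes
#' nothing.
#'
#' @param stats data.frame/data.table with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `alt_allele`, `beta`, `pvalue` and optionally `info`.
#' @param reference data.frame with columns `rsid`, `ref`, `alt` (e.g.
#'   derived from the 1000 Genomes panel).
#' @param info_threshold minimum imputation score kept (default 0.3).
#' @return list of class `gwas_qc` with `stats` (cleaned data.table) and
#'   `report` (named integer counts per removal class).
#' @export
qc_summary_stats <- function(stats, reference, info_threshold = 0.3) {
  req <- c("rsid", "chrom", "pos", "effect_allele", "alt_allele", "beta", "pvalue")
  miss <- setdiff(req, names(stats))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!all(c("rsid", "ref", "alt") %in% names(reference))) {
    stop("reference table needs columns rsid, ref, alt")
  }
  dt <- data.table::as.data.table(stats)
  rep_ <- c(n_input = nrow(dt))

  chrom_num <- suppressWarnings(as.integer(sub("^chr", "", as.character(dt$chrom))))
  auto <- !is.na(chrom_num) & chrom_num >= 1L & chrom_num <= 22L
  rep_["non_autosomal"] <- sum(!auto)
  dt <- dt[auto]; dt[, chrom := chrom_num[auto]]

  bases <- c("A", "C", "G", "T")
  bi <- dt$effect_allele %in% bases & dt$alt_allele %in% bases &
    dt$effect_allele != dt$alt_allele
  rep_["non_biallelic"] <- sum(!bi)
  dt <- dt[bi]

  dup <- dt$rsid %in% dt$rsid[duplicated(dt$rsid)]
  rep_["duplicate_rsid"] <- sum(dup)
  dt <- dt[!dup]

  if ("info" %in% names(dt)) {
    low <- !is.na(dt$info) & dt$info < info_threshold
    rep_["low_info"] <- sum(low)
    dt <- dt[!low]
  } else {
    rep_["low_info"] <- 0L
  }

  m <- match(dt$rsid, reference$rsid)
  in_ref <- !is.na(m)
  rep_["not_in_reference"] <- sum(!in_ref)
  dt <- dt[in_ref]; m <- m[in_ref]
  ref_a <- as.character(reference$ref[m])
  alt_a <- as.character(reference$alt[m])

  as_is <- dt$effect_allele == alt_a & dt$alt_allele == ref_a
  flip <- dt$effect_allele == ref_a & dt$alt_allele == alt_a
  rep_["allele_mismatch"] <- sum(!as_is & !flip)
  rep_["flipped"] <- sum(flip)
  dt[flip, `:=`(beta = -beta, effect_allele = alt_a[flip], alt_allele = ref_a[flip])]
  dt <- dt[as_is | flip]

  rep_["n_output"] <- nrow(dt)
  if (nrow(dt) == 0) warning("QC removed every record")
  structure(list(stats = dt[], report = rep_), class = "gwas_qc")
}

#' Read a table of locally correlated genomic regions
#'
#' Parses the region table produced by a local genetic-correlation scan
#' (chromosome, start, end, sign of correlation, q-value, optionally a
#' disease-pair tag). Coordinates are 1-based and inclusive at both ends.
#' The sign column accepts `+`/`-`, `+1`/`-1` or `1`/`-1`.
#'
#' @param path path to a TSV with columns `chrom`, `start`, `end`, `sign`,
#'   `qvalue` (and optionally `disease_pair`).
#' @return data.table with `chrom` (integer), `start`, `end`, `sign_`
#'   (+1/-1 integer) and `qvalue`.
#' @export
read_regions <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (nrow(dt) == 0) {
    return(data.table::data.table(chrom = integer(), start = integer(),
                                  end = integer(), sign_ = integer(),
                                  qvalue = numeric()))
  }
  req <- c("chrom", "start", "end", "sign", "qvalue")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("region file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(dt$start > dt$end)
  if (length(bad)) {
    stop(sprintf("malformed interval (start > end) at line %d", bad[1] + 1L))
  }
  s <- as.character(dt$sign)
  sign_ <- ifelse(s %in% c("+", "+1", "1"), 1L,
                  ifelse(s %in% c("-", "-1"), -1L, NA_integer_))
  if (anyNA(sign_)) stop("unrecognized sign value: ", s[which(is.na(sign_))[1]])
  out <- dt[, .(chrom = as.integer(chrom), start = as.integer(start),
                end = as.integer(end))]
  out[, sign_ := sign_]
  out[, qvalue := as.numeric(dt$qvalue)]
  if ("disease_pair" %in% names(dt)) out[, disease_pair := dt$disease_pair]
  out[]
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `entrez`, `chrom`, `start`, `end`
#'   (1-based, inclusive).
#' @return data.table with `entrez` as character.
#' @export
read_gene_annotations <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  req <- c("entrez", "chrom", "start", "end")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
  dt[, entrez := as.character(entrez)]
  dt[, chrom := suppressWarnings(as.integer(sub("^chr", "", as.character(chrom))))]
  dt[]
}

#' Map correlated regions to positionally overlapping genes
#'
#' A gene is mapped to a region when the gene body extended by `window_bp`
#' on both sides shares at least one base with the region; all coordinates
#' are 1-based and intervals inclusive, so a gap of exactly `window_bp`
#' still maps while `window_bp + 1` does not. By default only positively
#' correlated regions are used (genes under negatively correlated loci act
#' in opposite directions in the two diseases and are not useful for
#' repurposing).
#'
#' @param regions data.table from [read_regions()].
#' @param annotations data.table from [read_gene_annotations()].
#' @param window_bp symmetric window in base pairs (default 10000).
#' @param positive_only use only regions with sign +1 (default TRUE).
#' @return data.table with one row per mapped gene: `entrez`, `chrom`,
#'   `n_loci` and `locus` (semicolon-collapsed `chrom:start-end` list).
#' @export
map_regions_to_genes <- function(regions, annotations, window_bp = 10000,
                                 positive_only = TRUE) {
  reg <- data.table::as.data.table(regions)
  if (positive_only && nrow(reg)) reg <- reg[sign_ == 1L]
  empty <- data.table::data.table(entrez = character(), chrom = integer(),
                                  n_loci = integer(), locus = character())
  if (nrow(reg) == 0) return(empty)
  ann <- data.table::as.data.table(annotations)
  unknown <- is.na(ann$chrom)
  if (any(unknown)) {
    warning(sprintf("%d gene(s) with unknown chromosome skipped", sum(unknown)))
    ann <- ann[!unknown]
  }
  if (nrow(ann) == 0) return(empty)
  q <- ann[, .(entrez, chrom,
               win_start = pmax(1L, start - as.integer(window_bp)),
               win_end = end + as.integer(window_bp))]
  data.table::setkeyv(reg, c("chrom", "start", "end"))
  hits <- data.table::foverlaps(q, reg,
                                by.x = c("chrom", "win_start", "win_end"),
                                type = "any", nomatch = NULL)
  if (nrow(hits) == 0) return(empty)
  hits[, locus := sprintf("%d:%d-%d", chrom, start, end)]
  out <- hits[, .(n_loci = .N, locus = paste(sort(unique(locus)), collapse = ";")),
              by = .(entrez, chrom)]
  data.table::setorder(out, chrom, entrez)
  out[]
}

#' Read a MAGMA-style gene association table
#'
#' Whitespace-separated table with at least columns `GENE` and `P`
#' (the `.genes.out` layout: GENE CHR START STOP NSNPS ZSTAT P).
#'
#' @param path file path.
#' @return data.table with `entrez` (character) and `magma_p`.
#' @export
read_magma <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("GENE", "P") %in% names(dt))) {
    stop("MAGMA file must have columns GENE and P")
  }
  out <- dt[, .(entrez = as.character(GENE), magma_p = as.numeric(P))]
  out[]
}

#' Read an S-MultiXcan-style signed gene-regulation table
#'
#' @param path TSV with columns `gene`, `z_pd` (predisposing disease) and
#'   `z_bc` (breast cancer / target disease).
#' @return data.table with `entrez` (character), `z_pd`, `z_bc`.
#' @export
read_smultixcan <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  req <- c("gene", "z_pd", "z_bc")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("S-MultiXcan file missing column(s): ", paste(miss, collapse = ", "))
  out <- dt[, .(entrez = as.character(gene), z_pd = as.numeric(z_pd),
                z_bc = as.numeric(z_bc))]
  out[]
}

#' Filter locus genes down to the shared-gene set
#'
#' Keeps, among the positionally mapped candidate genes, those that are
#' (1) significantly associated with the predisposing disease after
#' Benjamini-Hochberg adjustment of the gene-based p-values (strictly
#' `p_adjusted < alpha`), and (2) predicted to be dysregulated in the same
#' direction in both diseases (equal, non-zero signs of the two signed
#' regulation statistics). The BH family is every gene in the supplied
#' statistics table (the genome-wide gene-based analysis), not only the
#' locus genes. Genes missing either statistic are dropped with a recorded
#' reason.
#'
#' @param candidates character vector of candidate Entrez IDs (or the
#'   data.table returned by [map_regions_to_genes()]).
#' @param gene_stats data.table with `entrez`, `magma_p` (or a
#'   pre-computed `magma_p_bh`), `z_pd`, `z_bc`. Supply the full table for
#'   the disease so the BH family is genome-wide.
#' @param alpha BH significance threshold (default 0.05).
#' @param disease_pair identifier stored on the result.
#' @return list of class `shared_gene_set`: `disease_pair`, `genes`
#'   (character), `provenance` (per-candidate data.table with the filter
#'   trail: `magma_p_bh`, `z_pd`, `z_bc`, `kept`, `reason`).
#' @export
filter_shared_genes <- function(candidates, gene_stats, alpha = 0.05,
                                disease_pair = NA_character_) {
  prov_extra <- NULL
  if (is.data.frame(candidates)) {
    prov_extra <- data.table::as.data.table(candidates)
    candidates <- as.character(prov_extra$entrez)
  }
  candidates <- unique(as.character(candidates))
  gs <- data.table::as.data.table(gene_stats)
  gs[, entrez := as.character(entrez)]
  if (!"magma_p_bh" %in% names(gs)) {
    if (!"magma_p" %in% names(gs)) stop("gene_stats needs magma_p or magma_p_bh")
    gs[, magma_p_bh := p.adjust(magma_p, method = "BH")]
  }
  prov <- data.table::data.table(entrez = candidates)
  m <- match(candidates, gs$entrez)
  prov[, magma_p_bh := gs$magma_p_bh[m]]
  prov[, z_pd := if ("z_pd" %in% names(gs)) gs$z_pd[m] else NA_real_]
  prov[, z_bc := if ("z_bc" %in% names(gs)) gs$z_bc[m] else NA_real_]
  prov[, reason := data.table::fcase(
    is.na(magma_p_bh), "no_association_stat",
    is.na(z_pd) | is.na(z_bc), "no_regulation_stat",
    magma_p_bh >= alpha, "not_significant",
    sign(z_pd) != sign(z_bc) | z_pd == 0 | z_bc == 0, "sign_discordant",
    default = "kept")]
  prov[, kept := reason == "kept"]
  if (!is.null(prov_extra) && "locus" %in% names(prov_extra)) {
    prov[, locus := prov_extra$locus[match(entrez, prov_extra$entrez)]]
  }
  structure(list(disease_pair = disease_pair,
                 genes = prov$entrez[prov$kept],
                 provenance = prov[]),
            class = "shared_gene_set")
}

#' Write a shared-gene set with its provenance trail
#' @param sgs a `shared_gene_set`.
#' @param path output TSV path.
#' @export
write_shared_genes <- function(sgs, path) {
  stopifnot(inherits(sgs, "shared_gene_set"))
  out <- data.table::copy(sgs$provenance)
  out[, disease_pair := sgs$disease_pair]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @export
print.shared_gene_set <- function(x, ...) {
  cat(sprintf("<shared_gene_set> %s: %d shared gene(s) of %d candidate(s)\n",
              x$disease_pair, length(x$genes), nrow(x$provenance)))
  invisible(x)
}
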