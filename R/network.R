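#' Load and clean a STRING-style protein-protein interaction network
#'
#' Reads a STRING-format links file (`protein1 protein2 combined_score`,
#' space-separated, integer scores on the 0--1000 scale) together with an
#' alias file mapping protein identifiers to Entrez gene IDs, and builds an
#' undirected, confidence-filtered gene network:
#'
#' * edges with `combined_score < min_score` are dropped (STRING's
#'   "high confidence" 0.7 corresponds to the default 700);
#' * protein IDs are mapped to Entrez IDs via alias rows whose source
#'   column matches `alias_source`; edges touching an unmapped protein are
#'   dropped and the node count is recorded;
#' * proteins sharing one Entrez ID are merged (edges unioned, max score);
#' * self-loops are removed and duplicate edges collapsed keeping the
#'   maximum score.
#'
#' @param links_path path to the links file.
#' @param alias_path path to the alias file (TSV: protein, alias, source);
#'   a leading `#` on the header line is tolerated.
#' @param min_score minimum combined score kept (integer, 0--1000).
#' @param alias_source source tag selecting Entrez rows in the alias file.
#' @return An object of class `ppi_network`: a list with `nodes` (character
#'   Entrez IDs, sorted numerically), `edges` (data.table `from`, `to`,
#'   `score` with `from < to` numerically), `degree` (named integer),
#'   `degree_bin` (`NULL` until [assign_degree_bins()] is called),
#'   `adjacency` (symmetric sparse 0/1 matrix), and bookkeeping counts.
#' @export
load_string_network <- function(links_path, alias_path, min_score = 700,
                                alias_source = "Entrez_Gene_ID") {
  links <- data.table::fread(links_path, header = TRUE)
  if (!all(c("protein1", "protein2", "combined_score") %in% names(links))) {
    stop("links file must have columns protein1, protein2, combined_score")
  }
  aliases <- data.table::fread(alias_path, header = TRUE)
  names(aliases) <- sub("^#+\\s*", "", names(aliases))
  if (ncol(aliases) < 3) stop("alias file needs three columns (protein, alias, source)")
  data.table::setnames(aliases, 1:3, c("protein", "alias", "source_tag"))
  map <- aliases[source_tag == alias_source, .(protein, entrez = as.character(alias))]
  if (nrow(map) == 0) {
    stop(sprintf("alias file has no rows with source '%s' (mapping column missing?)",
                 alias_source))
  }
  map <- unique(map, by = "protein")

  links <- links[combined_score >= min_score]
  prot <- unique(c(links$protein1, links$protein2))
  n_unmapped <- length(setdiff(prot, map$protein))
  links[, from := map$entrez[match(protein1, map$protein)]]
  links[, to := map$entrez[match(protein2, map$protein)]]
  edges <- links[!is.na(from) & !is.na(to),
                 .(from, to, score = as.integer(combined_score))]
  ## merging proteins onto one Entrez ID can create loops; drop them too
  edges <- edges[from != to]
  ## canonical orientation, then dedupe keeping the max score
  flip <- as.numeric(edges$from) > as.numeric(edges$to)
  tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]; edges$to[flip] <- tmp
  edges <- edges[, .(score = max(score)), by = .(from, to)]

  nodes <- unique(c(edges$from, edges$to))
  nodes <- nodes[order(as.numeric(nodes))]
  deg <- table(factor(c(edges$from, edges$to), levels = nodes))
  deg <- setNames(as.integer(deg), nodes)

  idx <- setNames(seq_along(nodes), nodes)
  adj <- Matrix::sparseMatrix(
    i = c(idx[edges$from], idx[edges$to]),
    j = c(idx[edges$to], idx[edges$from]),
    x = 1, dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes))

  .pd_msg("network: %d nodes, %d edges (min_score=%d, %d unmapped proteins dropped)",
          length(nodes), nrow(edges), min_score, n_unmapped)
  structure(list(nodes = nodes, edges = edges, degree = deg,
                 degree_bin = NULL, adjacency = adj,
                 min_score = min_score, n_unmapped = n_unmapped),
            class = "ppi_network")
}

#' Assign degree-quartile bins to network nodes
#'
#' Partitions the node set into (up to) four groups by degree quartile.
#' Equal degrees always share a bin, so the permutation null draws
#' topology-matched seeds; with fewer than four distinct quartile
#' boundaries the bins degenerate (with a warning) down to a single bin
#' when all degrees are equal.
#'
#' @param net a `ppi_network`.
#' @param n_bins number of quantile bins (default 4).
#' @return the network with `degree_bin` filled in (named integer, values
#'   `1..k` with `k <= n_bins`).
#' @export
assign_degree_bins <- function(net, n_bins = 4) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$degree) == 0) stop("network is empty")
  probs <- seq_len(n_bins - 1) / n_bins
  breaks <- unique(unname(quantile(net$degree, probs = probs, type = 7)))
  bin <- findInterval(net$degree, breaks, left.open = TRUE) + 1L
  bin <- match(bin, sort(unique(bin)))
  names(bin) <- names(net$degree)
  if (length(unique(bin)) < n_bins) {
    warning(sprintf("degenerate degree bins: only %d distinct bin(s)",
                    length(unique(bin))))
  }
  net$degree_bin <- bin
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges (combined_score >= %s)\n",
              length(x$nodes), nrow(x$edges), x$min_score %||% "?"))
  if (!is.null(x$degree_bin)) {
    cat("degree bins:", paste(table(x$degree_bin), collapse = " / "), "\n")
  }
  invisible(x)
}
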