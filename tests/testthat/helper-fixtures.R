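## Fixture builders shared across the suite. Everything is generated in
## code at test time; no binary or stored fixtures.

## Write STRING-format links + alias files for an explicit edge list of
## gene IDs; returns the file paths and the protein naming used.
string_files_from_edges <- function(from, to, score = 900,
                                    dir = tempfile("strnet"),
                                    unmapped = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  from <- as.character(from); to <- as.character(to)
  genes <- sort(unique(c(from, to)))
  prot <- setNames(sprintf("9606.ENSP%04d", seq_along(genes)), genes)
  score <- rep_len(score, length(from))
  links <- file.path(dir, "links.txt")
  writeLines(c("protein1 protein2 combined_score",
               paste(prot[from], prot[to], score)), links)
  mapped <- setdiff(genes, unmapped)
  aliases <- file.path(dir, "aliases.tsv")
  writeLines(c("#string_protein_id\talias\tsource",
               paste(prot[mapped], mapped, "Entrez_Gene_ID", sep = "\t"),
               paste(prot[genes], paste0("SYM", genes), "Gene_Symbol", sep = "\t")),
             aliases)
  list(links = links, aliases = aliases, prot = prot)
}

load_net <- function(from, to, score = 900, min_score = 700,
                     unmapped = character()) {
  f <- string_files_from_edges(from, to, score, unmapped = unmapped)
  load_string_network(f$links, f$aliases, min_score = min_score)
}

## Random Erdos-Renyi edge list with no isolated nodes (isolated nodes
## are attached to a random neighbor), as gene IDs "1".."n".
random_edges <- function(n, p = 0.15) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sel <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  present <- unique(as.vector(sel))
  for (i in setdiff(seq_len(n), present)) {
    sel <- rbind(sel, c(i, sample(setdiff(seq_len(n), i), 1)))
  }
  data.frame(from = as.character(sel[, 1]), to = as.character(sel[, 2]))
}

## Independent oracle for personalized PageRank: direct linear solve of
## (I - (1 - r) t(W)) s = r e_seed with W the row-stochastic transition
## matrix of the undirected graph.
ppr_solve_oracle <- function(net, seed, restart) {
  A <- as.matrix(net$adjacency)
  n <- nrow(A)
  W <- A / rowSums(A)
  e <- numeric(n)
  e[match(seed, net$nodes)] <- 1
  s <- solve(diag(n) - (1 - restart) * t(W), restart * e)
  setNames(as.numeric(s), net$nodes)
}

## Minimal ppi_network stand-in for operations that only consume the
## degree vector (degree-bin assignment).
net_with_degrees <- function(deg) {
  structure(list(nodes = names(deg), edges = NULL, degree = deg,
                 degree_bin = NULL, adjacency = NULL),
            class = "ppi_network")
}

## Small summary-statistics fixture with one record per QC removal class.
qc_fixture <- function() {
  stats <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs5", "rs6", "rs7", "rs8"),
    chrom = c("1", "X", "2", "3", "4", "4", "5", "6", "7"),
    pos = 1:9 * 1000L,
    effect_allele = c("A", "A", "AT", "A", "A", "A", "A", "A", "A"),
    alt_allele = c("G", "G", "G", "G", "G", "G", "G", "G", "G"),
    beta = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.5, 0.6, 0.7, 0.8),
    pvalue = rep(0.01, 9),
    info = c(1, 1, 1, 0.29, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  reference <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6", "rs8"),
    ref = c("A", "A", "A", "A", "A", "C", "G"),
    alt = c("G", "G", "G", "G", "G", "T", "A"),
    stringsAsFactors = FALSE)
  ## rs1 flip (effect==REF); rs2 chrX; rs3 non-biallelic; rs4 low info;
  ## rs5 duplicate; rs6 allele mismatch; rs7 not in reference;
  ## rs8 as-is (effect==ALT)
  list(stats = stats, reference = reference)
}
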