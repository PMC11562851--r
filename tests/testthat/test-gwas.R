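test_that("summary-statistics QC drops each removal class and counts it", {
  f <- qc_fixture()
  res <- qc_summary_stats(f$stats, f$reference, info_threshold = 0.3)
  expect_s3_class(res, "gwas_qc")
  expect_setequal(res$stats$rsid, c("rs1", "rs8"))
  expect_equal(unname(res$report["non_autosomal"]), 1)
  expect_equal(unname(res$report["non_biallelic"]), 1)
  expect_equal(unname(res$report["duplicate_rsid"]), 2)
  expect_equal(unname(res$report["low_info"]), 1)
  expect_equal(unname(res$report["not_in_reference"]), 1)
  expect_equal(unname(res$report["allele_mismatch"]), 1)
  expect_equal(unname(res$report["n_output"]), 2)
})

test_that("allele harmonization flips beta when effect matches reference REF", {
  f <- qc_fixture()
  res <- qc_summary_stats(f$stats, f$reference)
  rs1 <- res$stats[res$stats$rsid == "rs1", ]
  expect_equal(rs1$effect_allele, "G")
  expect_equal(rs1$alt_allele, "A")
  expect_equal(rs1$beta, -0.1)
  ## already-harmonized record untouched
  rs8 <- res$stats[res$stats$rsid == "rs8", ]
  expect_equal(rs8$beta, 0.8)
  expect_equal(rs8$effect_allele, "A")
})

test_that("QC respects the imputation-score boundary and optional column", {
  f <- qc_fixture()
  ## info = 0.29 dropped at threshold 0.3; exactly 0.3 kept
  f$stats$info[f$stats$rsid == "rs4"] <- 0.3
  res <- qc_summary_stats(f$stats, f$reference)
  expect_true("rs4" %in% res$stats$rsid)
  ## without an info column the filter does not apply
  res2 <- qc_summary_stats(f$stats[setdiff(names(f$stats), "info")], f$reference)
  expect_equal(unname(res2$report["low_info"]), 0)
})

test_that("QC is idempotent and fails loudly on missing columns", {
  f <- qc_fixture()
  once <- qc_summary_stats(f$stats, f$reference)
  twice <- qc_summary_stats(once$stats, f$reference)
  expect_equal(as.data.frame(twice$stats), as.data.frame(once$stats))
  expect_equal(unname(twice$report["flipped"]), 0)
  expect_error(qc_summary_stats(f$stats[-1], f$reference), "rsid")
  ref_all_mismatch <- data.frame(rsid = f$stats$rsid, ref = "C", alt = "T")
  expect_warning(qc_summary_stats(f$stats, ref_all_mismatch), "every record")
})

test_that("region tables parse signs, keep q-values, and reject bad intervals", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tsign\tqvalue",
               paste(1:7, c(100, 200, 300, 400, 500, 600, 700),
                     c(150, 250, 350, 450, 550, 650, 750),
                     c("+", "+", "+", "+", "+", "-", "-"),
                     c(0.01, 0.02, 0.03, 0.04, 0.05, 0.001, 0.002),
                     sep = "\t")), p)
  reg <- read_regions(p)
  expect_equal(nrow(reg), 7)
  expect_equal(sum(reg$sign_ == 1L), 5)
  expect_equal(reg$qvalue[6], 0.001)

  empty <- tempfile(fileext = ".tsv")
  writeLines("chrom\tstart\tend\tsign\tqvalue", empty)
  expect_equal(nrow(read_regions(empty)), 0)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tsign\tqvalue",
               "1\t100\t150\t+\t0.1", "2\t500\t400\t+\t0.1"), bad)
  expect_error(read_regions(bad), "line 3")
})

test_that("positional mapping is inclusive at the 10 kb window boundary", {
  reg <- data.table::data.table(chrom = 1L, start = 1000000L, end = 1050000L,
                                sign_ = 1L, qvalue = 0.01)
  ann <- data.table::data.table(
    entrez = c("10", "20", "30"),
    chrom = 1L,
    start = c(960000L, 960000L, 1010000L),
    end = c(990000L, 989999L, 1020000L))
  hit <- map_regions_to_genes(reg, ann, window_bp = 10000)
  expect_setequal(hit$entrez, c("10", "30"))  # gap 10,000 in; 10,001 out
  expect_false("20" %in% hit$entrez)
})

test_that("mapping uses only positively correlated regions by default", {
  reg <- data.table::data.table(chrom = 1L, start = 1000L, end = 2000L,
                                sign_ = -1L, qvalue = 0.01)
  ann <- data.table::data.table(entrez = "10", chrom = 1L,
                                start = 1500L, end = 1600L)
  expect_equal(nrow(map_regions_to_genes(reg, ann)), 0)
  both <- map_regions_to_genes(reg, ann, positive_only = FALSE)
  expect_equal(both$entrez, "10")
})

test_that("mapping grows monotonically with the window and skips unknown chromosomes", {
  set.seed(7)
  reg <- data.table::data.table(chrom = sample(1:3, 5, replace = TRUE),
                                start = sample(1:100000, 5),
                                sign_ = 1L, qvalue = 0.01)
  reg[, end := start + 20000L]
  ann <- data.table::data.table(entrez = as.character(1:50),
                                chrom = sample(c(1:3, NA), 50, replace = TRUE),
                                start = sample(1:120000, 50))
  ann[, end := start + 5000L]
  expect_warning(w0 <- map_regions_to_genes(reg, ann, window_bp = 0),
                 "unknown chromosome")
  expect_warning(w10 <- map_regions_to_genes(reg, ann, window_bp = 10000),
                 "unknown chromosome")
  expect_true(all(w0$entrez %in% w10$entrez))
})

test_that("shared-gene filter applies BH and sign concordance as specified", {
  ## BH worked example: p = (.01,.02,.03,.04), m = 4 =>
  ## min over i' >= i of p(i') * m / i' = .04 for every gene
  gs <- data.table::data.table(
    entrez = c("1", "2", "3", "4"),
    magma_p = c(0.01, 0.02, 0.03, 0.04),
    z_pd = c(1.2, 2.0, -1.5, 0.5),
    z_bc = c(0.8, -2.0, -0.7, 0))
  sgs <- filter_shared_genes(c("1", "2", "3", "4"), gs, alpha = 0.05,
                             disease_pair = "toy")
  expect_equal(sgs$provenance$magma_p_bh, rep(0.04, 4))
  ## gene 1: concordant, kept; gene 2: discordant (the probucol/ABCA1
  ## situation), dropped; gene 3: both negative, kept; gene 4: z = 0
  ## carries no direction, dropped
  expect_setequal(sgs$genes, c("1", "3"))
  expect_equal(sgs$provenance$reason[sgs$provenance$entrez == "2"],
               "sign_discordant")
  expect_equal(sgs$provenance$reason[sgs$provenance$entrez == "4"],
               "sign_discordant")
})

test_that("shared-gene filter handles thresholds, missing stats and empty input", {
  gs <- data.table::data.table(
    entrez = as.character(1:100),
    magma_p = c(1e-6, 0.04, runif(98, 0.5, 1)),
    z_pd = rep(1, 100), z_bc = rep(1, 100))
  sgs <- filter_shared_genes(as.character(1:3), gs, alpha = 0.05)
  ## gene 1 survives BH genome-wide; gene 2 (raw 0.04) does not once
  ## adjusted within the 100-gene family
  expect_true("1" %in% sgs$genes)
  expect_false("2" %in% sgs$genes)
  expect_equal(sgs$provenance$reason[2], "not_significant")
  ## candidate absent from the stats table
  sgs2 <- filter_shared_genes("999", gs)
  expect_length(sgs2$genes, 0)
  expect_equal(sgs2$provenance$reason, "no_association_stat")
  ## empty candidate set
  expect_length(filter_shared_genes(character(), gs)$genes, 0)
  ## output is always a subset of the input
  expect_true(all(sgs$genes %in% as.character(1:3)))
})

test_that("strict inequality is used at the BH threshold", {
  gs <- data.table::data.table(entrez = "1", magma_p_bh = 0.05,
                               magma_p = 0.05, z_pd = 1, z_bc = 1)
  expect_length(filter_shared_genes("1", gs, alpha = 0.05)$genes, 0)
  gs$magma_p_bh <- 0.0499
  expect_equal(filter_shared_genes("1", gs, alpha = 0.05)$genes, "1")
})
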