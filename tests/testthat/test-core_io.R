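test_that("read_panel keeps only biallelic genic SNPs and logs the rest", {
  ann <- make_annotation(n_genes = 2, span = 1000L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  make_vcf(vcf,
    chrom = rep("chr1", 6),
    pos = c(100, 200, 300, 400, 1500, 1800),
    ref = c("A", "AT", "G", "C", "T", "A"),
    alt = c("T", "A", "A,C", "G", "A", "G"),
    gts = list(
      c("0/0:10", "1/1:10", "0/0:10"),
      c("0/0:10", "0/0:10", "1/1:10"),   # indel -> dropped
      c("0/0:10", "1/1:10", "2/2:10"),   # triallelic -> dropped
      c("1/1:10", "0/0:10", "0/0:10"),
      c("0/0:10", "0/0:10", "1/1:10"),
      c("1/1:10", "1/1:10", "0/0:10")
    ),
    samples = c("s1", "s2", "s3"))
  g <- read_panel(vcf, ann)
  expect_equal(nrow(g$sites), 4)
  expect_equal(g$sites$pos, c(100L, 400L, 1500L, 1800L))
  expect_equal(g$sites$gene_id, c("g1", "g1", "g2", "g2"))
  log <- attr(g, "filter_log")
  expect_equal(log$n_indel, 1)
  expect_equal(log$n_multiallelic, 1)
  expect_equal(log$n_intergenic, 0)
})

test_that("read_panel masks low-depth genotypes and records het flags", {
  ann <- make_annotation(n_genes = 1, span = 1000L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  make_vcf(vcf,
    chrom = rep("chr1", 5),
    pos = c(100, 200, 300, 400, 500),
    ref = rep("A", 5), alt = rep("T", 5),
    gts = list(
      c("0/0:10", "1/1:2", "0/0:10"),    # depth 2 -> missing
      c("0/0:10", "0/1:10", "1/1:10"),   # het -> missing + flag
      c("0/0:10", "0/0:10", "1/1:10"),
      c("1/1:10", "0/0:10", "0/0:10"),
      c("0/0:10", "0/0:10", "./.:0")
    ),
    samples = c("s1", "s2", "s3"))
  g <- read_panel(vcf, ann, min_depth = 3)
  expect_true(is.na(g$calls["s2", 1]))
  expect_false(g$het_flags["s2", 1])
  expect_true(is.na(g$calls["s2", 2]))
  expect_true(g$het_flags["s2", 2])
  # 15 cells, one low-depth, one het, one ./. -> 12 non-missing
  expect_equal(sum(!is.na(g$calls)), 12)
})

test_that("read_panel never invents calls (round-trip from the generator)", {
  sim <- simulate_inbred_panel(panel_sim_config(
    n_lines = 12, d_frequency = 5 / 12, n_genes_mdl11 = 4, n_genes_flank = 6,
    sites_per_gene = 30, n_deleted_genes = 1, seed = 7))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(sim$genotypes, vcf)
  g2 <- read_panel(vcf, sim$annotation)
  expect_identical(g2$line_ids, sim$genotypes$line_ids)
  expect_identical(g2$sites$pos, sim$genotypes$sites$pos)
  expect_identical(unname(g2$calls), unname(sim$genotypes$calls))
  expect_identical(unname(g2$het_flags), unname(sim$genotypes$het_flags))
})

test_that("inbred site filters drop het sites, then thin-call sites", {
  # 12 lines x 4 sites; site 2 het in one line; site 3 called in 9 lines;
  # site 4 called in exactly 10 lines
  calls <- matrix(0L, 12, 4)
  calls[1, 2] <- NA
  het <- matrix(FALSE, 12, 4)
  het[1, 2] <- TRUE
  calls[1:3, 3] <- NA
  calls[1:2, 4] <- NA
  g <- make_gm(calls, het_flags = het)
  out <- apply_inbred_site_filters(g, min_lines = 10)
  expect_equal(out$sites$pos, c(100L, 400L))

  # identity on clean full matrices
  clean <- make_gm(matrix(0L, 12, 4))
  expect_identical(apply_inbred_site_filters(clean, 10)$calls, clean$calls)

  # idempotence
  once <- apply_inbred_site_filters(g, 10)
  twice <- apply_inbred_site_filters(once, 10)
  expect_identical(once$calls, twice$calls)
})

test_that("het-site removal precedes the min-lines count", {
  # site with one het call and 10 clean calls in 12 lines: a mask-then-count
  # filter would keep it (10 callable lines), the documented order drops it
  calls <- matrix(0L, 12, 2)
  calls[1, 1] <- NA    # het cell
  calls[12, 1] <- NA   # plain missing: 10 clean calls remain
  het <- matrix(FALSE, 12, 2)
  het[1, 1] <- TRUE
  g <- make_gm(calls, het_flags = het)
  out <- apply_inbred_site_filters(g, min_lines = 10)
  expect_equal(out$sites$pos, 200L)
  # the alternative order (count first, then mask het cells) disagrees here
  kept_by_masking <- colSums(!is.na(calls)) >= 10
  expect_true(kept_by_masking[1])
})

test_that("no-survivor filtering is an explicit error", {
  calls <- matrix(NA_integer_, 12, 2)
  g <- make_gm(calls)
  expect_error(apply_inbred_site_filters(g, 10), "no sites survive")
})

test_that("gene filter enforces the retained-site threshold per gene", {
  n_sites <- 200 + 150 + 100
  gene_id <- rep(c("g1", "g2", "g3"), c(200, 150, 100))
  calls <- matrix(0L, 4, n_sites)
  g <- make_gm(calls, gene_id = gene_id,
               pos = seq_len(n_sites) * 10L)
  ann <- make_annotation(n_genes = 3, span = 2000L)
  out <- apply_gene_filters(g, ann, min_sites = 150)
  expect_equal(sort(out$genes$gene_id[out$genes$kept]), c("g1", "g2"))
  expect_equal(nrow(out$genotypes$sites), 350)
  # 149 vs 150 boundary
  gene_id2 <- rep(c("g1", "g2"), c(149, 150))
  g2 <- make_gm(matrix(0L, 4, 299), gene_id = gene_id2,
                pos = seq_len(299) * 10L)
  out2 <- apply_gene_filters(g2, ann, min_sites = 150)
  expect_equal(out2$genes$kept, c(FALSE, TRUE))
  # identity when all genes pass
  out3 <- apply_gene_filters(g, ann, min_sites = 50)
  expect_equal(nrow(out3$genotypes$sites), n_sites)
  # unknown gene id is a validation error
  g_bad <- make_gm(matrix(0L, 4, 160), gene_id = "nope",
                   pos = seq_len(160) * 10L)
  expect_error(apply_gene_filters(g_bad, ann), "absent from annotation")
})

test_that("depth matrix reader restricts to exonic sites, keeps values", {
  ann <- as_gene_annotation(data.frame(
    gene_id = "g1", chrom = "chr1", start = 1L, end = 1000L,
    exons = "1-500", map_order = 1L, region = "OTHER",
    stringsAsFactors = FALSE))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(chrom = "chr1", pos = c(100L, 300L, 700L),
                    l1 = c(5, 8, 1), l2 = c(0, 12, 2))
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- read_depth_matrix(tsv, ann)
  expect_equal(nrow(d$sites), 2)  # pos 700 is intronic
  expect_equal(unname(d$depth), rbind(c(5, 8), c(0, 12)))
  # negative depth rejected
  tab$l1[1] <- -1
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_depth_matrix(tsv, ann), "non-negative")
})

test_that("depth path is independent of the genotype path", {
  # a site present in the depth table only is still usable
  sim <- simulate_inbred_panel(panel_sim_config(
    n_lines = 10, d_frequency = 0.4, n_genes_mdl11 = 3, n_genes_flank = 4,
    sites_per_gene = 20, n_deleted_genes = 1, seed = 3))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_depth_tsv(sim$depth, tsv)
  d <- read_depth_matrix(tsv, sim$annotation)
  expect_equal(dim(d$depth), dim(sim$depth$depth))
  expect_equal(unname(d$depth), unname(sim$depth$depth), tolerance = 1e-6)
})

test_that("malformed VCF input is rejected with a message", {
  ann <- make_annotation()
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "at all"), bad)
  expect_error(read_panel(bad, ann))
})

test_that("GFF3 import builds an equivalent annotation table", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=gA",
    "chr1\tsrc\texon\t1\t400\t.\t+\t.\tParent=gA",
    "chr1\tsrc\texon\t600\t1000\t.\t+\t.\tParent=gA",
    "chr1\tsrc\tgene\t2001\t3000\t.\t-\t.\tID=gB",
    "chr1\tsrc\texon\t2001\t3000\t.\t-\t.\tParent=gB"
  ), gff)
  ann <- annotation_from_gff3(gff, mdl11_genes = "gA")
  expect_equal(ann$gene_id, c("gA", "gB"))
  expect_equal(ann$region, c("MDL11", "OTHER"))
  expect_equal(ann$map_order, c(1L, 2L))
  expect_equal(nrow(ann$exon_list[[1]]), 2)
  loc <- centrodrive:::locate_in_genes(rep("chr1", 2), c(500L, 700L), ann)
  expect_equal(loc$exonic, c(FALSE, TRUE))
})
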