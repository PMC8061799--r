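test_that("derived-variant counting applies the het-gene exclusion", {
  # 13 identical lines: S = 0, empty table
  g0 <- make_gm(matrix(0L, 13, 20))
  dv0 <- count_derived_variants(g0)
  expect_equal(nrow(dv0$table), 0)
  expect_equal(dv0$sum_x, 0)
  expect_equal(dv0$L, 20)

  # a gene with 6 het exonic sites is dropped entirely from L
  calls <- matrix(0L, 13, 30)
  het <- matrix(FALSE, 13, 30)
  het[1, 1:6] <- TRUE          # 6 het sites in g1
  calls[1, 1:6] <- NA
  het[2, 16] <- TRUE           # 1 het site in g2: only the site is dropped
  calls[2, 16] <- NA
  g <- make_gm(calls, gene_id = rep(c("g1", "g2"), each = 15),
               het_flags = het)
  dv <- count_derived_variants(g, max_het_per_gene = 5)
  expect_equal(dv$L, 14)       # g2 minus its single het site
  expect_equal(dv$n_genes_excluded, 1)

  # all sites het-excluded -> explicit error
  het_all <- matrix(TRUE, 13, 4)
  g_bad <- make_gm(matrix(NA_integer_, 13, 4), het_flags = het_all)
  expect_error(count_derived_variants(g_bad, max_het_per_gene = 99),
               "cannot date")
})

test_that("derived counts use the majority-ancestral rule with ref ties", {
  # 13 lines: 8 singleton sites + 1 doubleton -> S = 9, sum(x) = 10
  calls <- matrix(0L, 13, 20)
  for (k in 1:8) calls[k, k] <- 1L
  calls[c(1, 2), 9] <- 1L
  dv <- count_derived_variants(make_gm(calls))
  expect_equal(nrow(dv$table), 9)
  expect_equal(dv$sum_x, 10)
  expect_equal(dv$L, 20)
  expect_true(all(dv$table$ancestral == "A"))

  # exact tie (2/2 among 4 called) resolves toward the reference allele
  calls2 <- matrix(NA_integer_, 13, 1)
  calls2[1:4, 1] <- c(1L, 1L, 0L, 0L)
  dv2 <- count_derived_variants(make_gm(calls2))
  expect_equal(dv2$table$ancestral, "A")
  expect_equal(dv2$table$derived_count, 2L)
})

test_that("Thomson estimator reproduces its closed form across a mu grid", {
  th <- thomson_age(10, n = 13, mu = c(1.5e-8, 0.2e-8), L = 256867)
  expect_equal(round(th$t_hat), c(200, 1497))
  expect_equal(thomson_age(0, n = 13, mu = 1e-8, L = 100)$t_hat, 0)
  expect_error(thomson_age(10, n = 13, mu = 0, L = 100), "mu")
  expect_error(thomson_age(10, n = 13, mu = 1e-8, L = 0), "L")
  # linear in sum_x, inverse in n, mu, L
  set.seed(1)
  for (i in 1:10) {
    sx <- rpois(1, 20); n <- sample(5:30, 1)
    mu <- runif(1, 1e-9, 1e-7); L <- sample(1e4:1e6, 1)
    t1 <- thomson_age(sx, n = n, mu = mu, L = L)$t_hat
    expect_equal(thomson_age(2 * sx, n = n, mu = mu, L = L)$t_hat, 2 * t1)
    expect_equal(thomson_age(sx, n = 2 * n, mu = mu, L = L)$t_hat, t1 / 2)
    expect_equal(thomson_age(sx, n = n, mu = 2 * mu, L = L)$t_hat, t1 / 2)
    expect_equal(thomson_age(sx, n = n, mu = mu, L = 2 * L)$t_hat, t1 / 2)
  }
})

test_that("shared core segments break at the first informative mismatch", {
  # identical lines span the full genotyped range
  g0 <- make_gm(matrix(0L, 3, 5), pos = c(100L, 200L, 300L, 400L, 500L))
  s0 <- shared_core_segment(g0, c("line1", "line2"), focal_pos = 250)
  expect_equal(c(s0$start, s0$end), c(100L, 500L))

  # two lines differing only at the 3rd of 5 SNPs, focal at SNP 1:
  # segment ends at the midpoint before SNP 3
  calls <- matrix(0L, 2, 5)
  calls[2, 3] <- 1L
  g <- make_gm(calls, pos = c(100L, 200L, 300L, 400L, 500L))
  s <- shared_core_segment(g, c("line1", "line2"), focal_pos = 100)
  expect_equal(s$start, 100L)
  expect_equal(s$end, 250L)
  expect_equal(s$n_snps, 2L)

  # mismatch at the SNP nearest the focal position -> zero length
  s2 <- shared_core_segment(g, c("line1", "line2"), focal_pos = 310)
  expect_equal(s2$length_bp, 0L)

  # monotonicity: adding lines never lengthens the core
  set.seed(5)
  for (i in 1:10) {
    cal <- matrix(rbinom(6 * 30, 1, 0.5), 6, 30)
    gg <- make_gm(cal, pos = seq_len(30) * 50L)
    l2 <- shared_core_segment(gg, c("line1", "line2"), 750)$length_bp
    l3 <- shared_core_segment(gg, c("line1", "line2", "line3"), 750)$length_bp
    expect_lte(l3, l2)
  }
})

test_that("haplotype group assignment recovers block structure", {
  # two blocks of identical lines -> two groups spanning the region
  calls <- rbind(matrix(0L, 3, 20),
                 matrix(rep(c(0L, 1L), 10), 3, 20, byrow = TRUE))
  g <- make_gm(calls, pos = seq_len(20) * 100L)
  hg <- assign_haplotype_groups(g, focal_pos = 1000, match_snps = 3)
  expect_equal(length(hg$groups), 2)
  expect_equal(sort(vapply(hg$groups, length, integer(1))), c(3L, 3L))

  # all-distinct lines with min_group = 2 -> no groups, all singletons
  set.seed(9)
  cal <- matrix(rbinom(5 * 40, 1, 0.5), 5, 40)
  g2 <- make_gm(cal, pos = seq_len(40) * 100L)
  hg2 <- assign_haplotype_groups(g2, focal_pos = 2000, match_snps = 6)
  expect_equal(length(hg2$groups), 0)
  expect_equal(sort(hg2$singletons), sort(g2$line_ids))
})

test_that("haplotype-length dating inverts genetic length", {
  ages <- haplotype_age_from_length(c(221.1, 164.3), c(150, 1000))
  expect_equal(round(ages$t[ages$length_kb == 221.1 & ages$kb_per_cM == 1000]),
               452)
  expect_equal(round(ages$t[ages$length_kb == 164.3 & ages$kb_per_cM == 150]),
               91)
  expect_equal(haplotype_age_from_length(100, 100)$t, 100)
  expect_error(haplotype_age_from_length(0, 100), "length_kb")
  expect_error(haplotype_age_from_length(100, -1), "kb_per_cM")
  # strictly decreasing in length, increasing in rate
  t_len <- haplotype_age_from_length(c(50, 100, 200), 500)$t
  expect_true(all(diff(t_len) < 0))
  t_rate <- haplotype_age_from_length(100, c(150, 500, 1000))$t
  expect_true(all(diff(t_rate) > 0))
})

test_that("swept-flank generator and dating invert each other", {
  # pooled mean group length across replicates recovers the true age
  est <- vapply(1:6, function(i) {
    fs <- simulate_swept_flank_haplotypes(
      n_lines = 30, true_age = 300, kb_per_cM = 500, region_kb = 3000,
      marker_spacing_kb = 1, seed = 400 + i)
    hg <- assign_haplotype_groups(fs$genotypes,
                                  focal_pos = fs$truth$focal_pos)
    hg$mean_length_bp
  }, numeric(1))
  t_hat <- 100 * 500 / (mean(est) / 1000)
  expect_lt(abs(t_hat - 300) / 300, 0.25)
})
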