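test_that("drive strength inverts allele counts under Mendelian pollen", {
  expect_equal(estimate_drive_strength(c(29, 50, 21)), 0.58)
  expect_equal(estimate_drive_strength(c(25, 50, 25)), 0.5)
  expect_equal(estimate_drive_strength(c(40, 0, 0)), 1)      # clipped
  expect_equal(estimate_drive_strength(c(0, 0, 40)), 0)      # clipped
  expect_true(is.na(estimate_drive_strength(c(0, 0, 0))))
  m <- rbind(c(29, 50, 21), c(25, 50, 25))
  expect_equal(estimate_drive_strength(m), c(0.58, 0.5))
  expect_error(estimate_drive_strength(c(-1, 2, 3)), "non-negative")
})

test_that("drive strength estimator is nearly unbiased at large families", {
  set.seed(15)
  for (f in c(0.73, 0.93)) {
    est <- replicate(300, {
      cnt <- as.integer(rmultinom(1, 1000, c(f / 2, 0.5, (1 - f) / 2)))
      estimate_drive_strength(cnt)
    })
    expect_lt(abs(mean(est) - f), 0.01)
  }
})

test_that("genotype hardening is strict at the threshold", {
  expect_equal(harden_genotype_calls(c(0.9, 0.05, 0.05)), "GG")
  expect_true(is.na(harden_genotype_calls(c(0.8, 0.1, 0.1))))
  expect_true(is.na(harden_genotype_calls(c(0.34, 0.33, 0.33))))
  expect_equal(harden_genotype_calls(c(0.05, 0.05, 0.9)), "NN")
  expect_error(harden_genotype_calls(c(0.5, 0.2, 0.2)), "sum to 1")
  m <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.85, 0.05))
  expect_equal(harden_genotype_calls(m), c("GG", "NG"))
})

test_that("LOD scan equals an independent nested least-squares oracle", {
  set.seed(33)
  cs <- simulate_f2_cross(cross_sim_config(
    n_f2 = 30, marker_map = default_marker_map(1, 10, 10),
    family_range = c(14, 14), miscall_rate = 0, missing_rate = 0, seed = 2))
  lp <- lod_scan(cs$f2, min_family = 1)
  y <- estimate_drive_strength(cs$f2$f3_counts)
  cof <- as.numeric(cs$f2$mdl11 == "Dd")
  for (j in c(1, 5, 10)) {
    dos <- 2 * cs$f2$marker_probs[, j, 1] + cs$f2$marker_probs[, j, 2]
    expect_equal(lp$lod[j], oracle_lod(y, cof, dos), tolerance = 1e-10)
  }
})

test_that("LOD scan is invariant to which allele is labelled N vs G", {
  set.seed(12)
  cs <- simulate_f2_cross(cross_sim_config(
    n_f2 = 40, marker_map = default_marker_map(2, 8, 8),
    family_range = c(12, 16), seed = 3))
  lp1 <- lod_scan(cs$f2, min_family = 1)
  flipped <- cs$f2$marker_probs[, , 3:1]  # swap GG and NN
  f2b <- f2_records(cs$f2$f2_id, cs$f2$mdl11, flipped, cs$f2$marker_map,
                    cs$f2$f3_counts)
  lp2 <- lod_scan(f2b, min_family = 1)
  expect_equal(lp1$lod, lp2$lod, tolerance = 1e-10)
})

test_that("a constant phenotype gives LOD 0 everywhere", {
  set.seed(8)
  cs <- simulate_f2_cross(cross_sim_config(
    n_f2 = 25, marker_map = default_marker_map(1, 6, 10),
    family_range = c(12, 12), seed = 9))
  f3 <- matrix(rep(c(3L, 6L, 3L), each = 25), 25, 3)  # all f_hat = 0.5
  f2c <- f2_records(cs$f2$f2_id, cs$f2$mdl11, cs$f2$marker_probs,
                    cs$f2$marker_map, f3)
  lp <- lod_scan(f2c, min_family = 1)
  expect_true(all(abs(lp$lod) < 1e-8))
})

test_that("families below the progeny threshold never enter the scan", {
  set.seed(44)
  cs <- simulate_f2_cross(cross_sim_config(
    n_f2 = 60, marker_map = default_marker_map(1, 6, 10),
    family_range = c(10, 14), seed = 13))
  n_prog <- rowSums(cs$f2$f3_counts)
  lp <- lod_scan(cs$f2, min_family = 12)
  expect_equal(attr(lp, "n_used"), sum(n_prog >= 12))
  expect_error(lod_scan(cs$f2, min_family = 17), "fewer than 20 eligible")
})

test_that("LOD smoothing uses a truncated centred window", {
  expect_equal(smooth_lod(rep(2, 6), 4), rep(2, 6))
  expect_equal(smooth_lod(c(1, 5, 3), 1), c(1, 5, 3))
  expect_equal(smooth_lod(c(0, 0, 4, 0, 0), 4),
               c(4 / 3, 1, 1, 4 / 3, 0))
  expect_equal(smooth_lod(c(1, 2, 3), 10), rep(2, 3))
  expect_error(smooth_lod(1:3, 0), "window")
})

test_that("two-way ANOVA matches the balanced-design decomposition", {
  # balanced 4 x 2 layout, 3 replicates: hand-computed sums of squares
  a <- factor(rep(rep(c("GG", "NG160", "NG767", "NN"), each = 2), 3))
  b <- factor(rep(c("DDm", "Dd"), 12))
  mu_a <- c(GG = 0.6, NG160 = 0.7, NG767 = 0.8, NN = 0.9)
  mu_b <- c(DDm = -0.1, Dd = 0.1)
  set.seed(99)
  y <- mu_a[as.character(a)] + mu_b[as.character(b)] + rnorm(24, 0, 0.05)
  tab <- two_way_anova(y, a, b)
  # brute-force balanced decomposition
  gm <- mean(y)
  ssa <- sum(tapply(y, a, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, b, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, interaction(a, b), mean)
  ssc <- 3 * sum((cellm - gm)^2)
  ssab <- ssc - ssa - ssb
  expect_equal(tab$sum_sq[tab$term == "factor_a"], ssa, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "factor_b"], ssb, tolerance = 1e-8)
  expect_equal(tab$sum_sq[tab$term == "interaction"], ssab, tolerance = 1e-8)
  expect_equal(tab$df[tab$term == "factor_a"], 3)
  expect_equal(tab$df[tab$term == "interaction"], 3)
})

test_that("additive zero-noise data have no interaction sum of squares", {
  a <- factor(rep(c("x", "y"), each = 4))
  b <- factor(rep(c("u", "v"), 4))
  y <- ifelse(a == "x", 1, 2) + ifelse(b == "u", 0, 0.5)
  tab <- two_way_anova(y, a, b)
  expect_lt(tab$sum_sq[tab$term == "interaction"], 1e-20)
})

test_that("ANOVA F statistics are calibrated under the null", {
  set.seed(123)
  ps <- replicate(200, {
    a <- factor(sample(rep(1:4, 10)))
    b <- factor(sample(rep(1:2, 20)))
    y <- rnorm(40)
    two_way_anova(y, a, b)$p_value[1]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("empty interaction cells fall back to the additive model", {
  a <- factor(c("x", "x", "y", "y", "x", "x"))
  b <- factor(c("u", "u", "u", "u", "v", "v"))  # no y:v cell
  y <- c(1, 1.1, 2, 2.1, 1.5, 1.4)
  tab <- two_way_anova(y, a, b)
  expect_true(is.na(tab$sum_sq[tab$term == "interaction"]))
  expect_false(is.na(tab$sum_sq[tab$term == "factor_a"]))
})
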