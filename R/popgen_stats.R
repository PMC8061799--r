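# Per-gene diversity, divergence, LD and bootstrap machinery for haploid
# panels with missing data. Sample size is recomputed per site everywhere.

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Per-gene nucleotide diversity and Tajima's D
#'
#' Nucleotide diversity is Nei's per-site heterozygosity, missing-data aware:
#' at each site with per-site sample size `n_s >= 2` and allele counts `a`,
#' `b`, the contribution is `a*b / choose(n_s, 2)`; the per-gene value divides
#' the summed contributions by the number of usable sites. Sites with fewer
#' than two calls are excluded from both numerator and denominator and
#' counted in `n_flagged`. Tajima's D uses the standard constants evaluated
#' at the per-gene mean per-site sample size rounded to the nearest integer,
#' and is `NA` (undefined) when no site segregates.
#'
#' @param g A [genotype_matrix()] restricted to a single gene.
#' @param gene_id Gene label for the output; defaults to the sites' gene id.
#' @param region Optional region label carried through to the output.
#' @return One-row data frame: `gene_id`, `region`, `n_lines_used` (mean
#'   per-site sample size), `n_sites` (usable sites), `n_flagged`, `S`, `pi`,
#'   `tajima_d`.
#' @export
gene_diversity <- function(g, gene_id = NULL, region = NA_character_) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$sites) < 1) stop("gene must have at least one retained site")
  if (is.null(gene_id)) {
    gene_id <- unique(g$sites$gene_id)
    gene_id <- if (length(gene_id) == 1) gene_id else NA_character_
  }
  sc <- site_counts(g)
  usable <- sc$n_called >= 2L
  n_use <- sum(usable)
  if (n_use == 0L) {
    return(data.frame(gene_id = gene_id, region = region,
                      n_lines_used = NA_real_, n_sites = 0L,
                      n_flagged = sum(!usable), S = 0L,
                      pi = NA_real_, tajima_d = NA_real_,
                      stringsAsFactors = FALSE))
  }
  n_s <- sc$n_called[usable]
  a <- sc$n_alt[usable]
  b <- n_s - a
  pi_site <- a * b / choose(n_s, 2)
  S <- sum(a > 0L & a < n_s)
  pi_total <- sum(pi_site)
  n_mean <- mean(n_s)
  taj <- NA_real_
  if (S > 0L) {
    nn <- max(2L, as.integer(round(n_mean)))
    if (nn >= 3L) {
      k <- tajima_constants(nn)
      v <- k$e1 * S + k$e2 * S * (S - 1)
      if (v > 0) taj <- (pi_total - S / k$a1) / sqrt(v)
    }
  }
  data.frame(gene_id = gene_id, region = region, n_lines_used = n_mean,
             n_sites = n_use, n_flagged = sum(!usable), S = S,
             pi = pi_total / n_use, tajima_d = taj, stringsAsFactors = FALSE)
}

#' Diversity statistics for every gene in a panel
#'
#' @param g A filtered [genotype_matrix()] whose sites carry `gene_id`.
#' @param annotation Optional `gene_annotation` supplying region labels.
#' @return Data frame with one [gene_diversity()] row per gene, ordered by
#'   map position.
#' @export
gene_diversity_table <- function(g, annotation = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  gid <- g$sites$gene_id
  genes <- unique(gid)
  rows <- lapply(genes, function(gg) {
    region <- NA_character_
    if (!is.null(annotation)) {
      m <- match(gg, annotation$gene_id)
      if (!is.na(m)) region <- annotation$region[m]
    }
    gene_diversity(subset_genotypes(g, site_idx = gid == gg),
                   gene_id = gg, region = region)
  })
  out <- do.call(rbind, rows)
  if (!is.null(annotation)) {
    m <- match(out$gene_id, annotation$gene_id)
    o <- order(annotation$chrom[m], annotation$map_order[m])
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Between-class divergence (d_xy) for one gene
#'
#' Mean over sites of the fraction of mismatching cross-class pairs,
#' `(x_A*(n_B-x_B) + (n_A-x_A)*x_B) / (n_A*n_B)`, using per-site non-missing
#' sample sizes. Sites where either class has no call are excluded from both
#' numerator and denominator; if no site is usable the result is `NA`
#' (undefined), never 0.
#'
#' @param gA,gB [genotype_matrix()] objects for the two line classes,
#'   restricted to the same gene and the same site set.
#' @return Scalar per-site d_xy (or `NA`).
#' @export
dxy_between_classes <- function(gA, gB) {
  stopifnot(inherits(gA, "genotype_matrix"), inherits(gB, "genotype_matrix"))
  if (nrow(gA$sites) != nrow(gB$sites) ||
      !all(gA$sites$pos == gB$sites$pos & gA$sites$chrom == gB$sites$chrom)) {
    stop("the two class matrices must cover identical sites")
  }
  sa <- site_counts(gA)
  sb <- site_counts(gB)
  ok <- sa$n_called >= 1L & sb$n_called >= 1L
  if (!any(ok)) return(NA_real_)
  xa <- sa$n_alt[ok]; na <- sa$n_called[ok]
  xb <- sb$n_alt[ok]; nb <- sb$n_called[ok]
  d <- (xa * (nb - xb) + (na - xa) * xb) / (na * nb)
  sum(d) / sum(ok)
}

#' Per-gene d_xy between two line classes across a panel
#'
#' @param g A filtered [genotype_matrix()].
#' @param panel A `line_panel` data frame assigning classes.
#' @param class_a,class_b Class labels; defaults `D` and `D_MINUS`.
#' @return Data frame `gene_id`, `dxy`.
#' @export
dxy_table <- function(g, panel, class_a = "D", class_b = "D_MINUS") {
  la <- intersect(panel$line_id[panel$class == class_a], g$line_ids)
  lb <- intersect(panel$line_id[panel$class == class_b], g$line_ids)
  if (!length(la) || !length(lb)) stop("both classes need at least one line")
  gid <- g$sites$gene_id
  genes <- unique(gid)
  dxy <- vapply(genes, function(gg) {
    idx <- gid == gg
    dxy_between_classes(subset_genotypes(g, la, idx),
                        subset_genotypes(g, lb, idx))
  }, numeric(1))
  data.frame(gene_id = genes, dxy = dxy, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mean r-squared between all SNP pairs of gene pairs
#'
#' r-squared is the squared Pearson correlation of the 0/1 haploid codes
#' (equivalent to `D^2/(p1*q1*p2*q2)`), computed per SNP pair on the lines
#' non-missing at both sites. Pairs with fewer than `min_joint` jointly
#' called lines, or monomorphic among the jointly called lines, are skipped
#' and do not count toward `n_pairs`.
#'
#' @param g A [genotype_matrix()].
#' @param genes Character vector of gene ids to include (default: all genes
#'   with at least one polymorphic site).
#' @param min_joint Minimum jointly genotyped lines per SNP pair; default 4.
#' @return Data frame of class `gene_pair_ld`: `gene_a`, `gene_b`,
#'   `mean_r2`, `n_pairs` (unordered gene pairs, including self pairs
#'   excluded).
#' @export
gene_pair_ld <- function(g, genes = NULL, min_joint = 4) {
  stopifnot(inherits(g, "genotype_matrix"))
  gid <- g$sites$gene_id
  sc <- site_counts(g)
  poly <- sc$segregating
  if (is.null(genes)) genes <- unique(gid[poly])
  idx_by_gene <- lapply(genes, function(gg) which(gid == gg & poly))
  names(idx_by_gene) <- genes
  keep <- lengths(idx_by_gene) > 0
  genes <- genes[keep]
  idx_by_gene <- idx_by_gene[keep]
  if (length(genes) < 2) stop("need at least two genes with polymorphic sites")
  res <- list()
  k <- 0L
  for (i in seq_len(length(genes) - 1)) {
    A <- g$calls[, idx_by_gene[[i]], drop = FALSE]
    okA <- !is.na(A)
    for (j in seq(i + 1, length(genes))) {
      B <- g$calls[, idx_by_gene[[j]], drop = FALSE]
      r2 <- suppressWarnings(
        stats::cor(A, B, use = "pairwise.complete.obs")
      )^2
      njoint <- crossprod(okA, !is.na(B))
      r2[njoint < min_joint] <- NA
      if (all(is.na(r2))) next
      k <- k + 1L
      res[[k]] <- data.frame(gene_a = genes[i], gene_b = genes[j],
                             mean_r2 = mean(r2, na.rm = TRUE),
                             n_pairs = sum(!is.na(r2)),
                             stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, res) else
    data.frame(gene_a = character(), gene_b = character(),
               mean_r2 = numeric(), n_pairs = integer())
  class(out) <- c("gene_pair_ld", "data.frame")
  out
}

#' Fraction of polymorphic sites matching a reference line
#'
#' For each line and gene, the fraction of panel-polymorphic sites (both
#' alleles observed among non-missing calls) at which the line carries the
#' same allele as `ref_line`, over sites where both the line and the
#' reference are genotyped. Cells supported by fewer than `min_poly` such
#' sites are `NA` (missing), mirroring haplotype-structure displays.
#'
#' @param g A [genotype_matrix()].
#' @param ref_line Line id of the reference individual.
#' @param min_poly Minimum scored polymorphic sites per line x gene; default 7.
#' @return Numeric matrix lines x genes of match fractions (with `NA`).
#' @export
reference_match_fraction <- function(g, ref_line, min_poly = 7) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!ref_line %in% g$line_ids) stop("ref_line not in panel: ", ref_line)
  sc <- site_counts(g)
  poly <- sc$segregating
  gid <- g$sites$gene_id
  genes <- unique(gid)
  ref <- g$calls[ref_line, ]
  out <- matrix(NA_real_, length(g$line_ids), length(genes),
                dimnames = list(g$line_ids, genes))
  for (j in seq_along(genes)) {
    idx <- which(gid == genes[j] & poly & !is.na(ref))
    if (!length(idx)) next
    sub <- g$calls[, idx, drop = FALSE]
    refv <- matrix(ref[idx], nrow(sub), length(idx), byrow = TRUE)
    scored <- !is.na(sub)
    n_scored <- rowSums(scored)
    frac <- rowSums(sub == refv, na.rm = TRUE) / n_scored
    frac[n_scored < min_poly] <- NA_real_
    out[, j] <- frac
  }
  out
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples `length(values)` items with replacement `n_boot` times and takes
#' percentile bounds of the resampled means. Deterministic given `seed`.
#' (Resampling n of n *without* replacement would reproduce the sample mean
#' identically; the standard percentile bootstrap is used.)
#'
#' @param values Numeric vector (non-finite values dropped).
#' @param n_boot Number of bootstrap replicates; default 1000.
#' @param level Coverage level; default 0.95.
#' @param seed Optional integer seed.
#' @return List of class `bootstrap_ci`: `mean`, `lo`, `hi`, `se`
#'   (bootstrap SD of the mean), `n_boot`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000, level = 0.95,
                              seed = NULL) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("need at least one finite value")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(n_boot), function(i) {
    mean(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  qs <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  structure(list(mean = mean(values), lo = qs[1], hi = qs[2],
                 se = stats::sd(means), n_boot = n_boot),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("mean %.6g  [%.6g, %.6g]  (percentile bootstrap, N = %d)\n",
              x$mean, x$lo, x$hi, x$n_boot))
  invisible(x)
}

#' Region-level diversity summary with bootstrap intervals
#'
#' Summarises per-gene statistics by region (the structure of a
#' diversity-by-region table): mean, bootstrap SE and percentile CI of the
#' per-gene means.
#'
#' @param div Output of [gene_diversity_table()] (must carry `region`).
#' @param stat Column to summarise; default `"pi"`.
#' @param n_boot,level,seed Passed to [bootstrap_mean_ci()].
#' @return Data frame `region`, `n_genes`, `mean`, `se`, `lo`, `hi`.
#' @export
region_summary <- function(div, stat = "pi", n_boot = 1000, level = 0.95,
                           seed = NULL) {
  stopifnot(stat %in% names(div))
  regions <- unique(div$region[!is.na(div$region)])
  rows <- lapply(seq_along(regions), function(i) {
    v <- div[[stat]][div$region == regions[i]]
    v <- v[is.finite(v)]
    ci <- bootstrap_mean_ci(v, n_boot = n_boot, level = level,
                            seed = if (is.null(seed)) NULL else seed + i)
    data.frame(region = regions[i], n_genes = length(v), mean = ci$mean,
               se = ci$se, lo = ci$lo, hi = ci$hi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
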