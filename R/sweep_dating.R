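# Two complementary sweep clocks: mutation accumulation on a non-recombining
# haplotype (Thomson TMRCA) and recombination-driven haplotype-length decay
# around a focal gene. Generations are equated with years (annual plant).

#' Count derived variants among focal-class lines
#'
#' Restricts a focal-class panel to exonic genic positions, removes sites with
#' any heterozygous flag, and drops entire genes with more than
#' `max_het_per_gene` heterozygous exonic sites (clusters of residual hets
#' typically mark collapsed copy-number variants whose apparent SNVs are
#' artefacts). The retained positions define the high-confidence locus length
#' `L`; at each segregating site the derived allele is called against the
#' inferred ancestral allele (majority allele among the focal lines; exact
#' ties broken toward the reference allele).
#'
#' @param g A [genotype_matrix()] already restricted to the focal-class lines.
#' @param annotation A `gene_annotation` (used only for validation; sites must
#'   carry `gene_id`).
#' @param max_het_per_gene Maximum heterozygous exonic sites tolerated per
#'   gene; default 5.
#' @return Object of class `derived_variant_table`: list with `table` (data
#'   frame `chrom`, `pos`, `ref`, `alt`, `ancestral`, `derived_count`,
#'   `n_called`), `L` (retained positions), `n` (lines), `sum_x` and
#'   `n_genes_excluded`.
#' @export
count_derived_variants <- function(g, annotation = NULL,
                                   max_het_per_gene = 5) {
  stopifnot(inherits(g, "genotype_matrix"))
  ex <- which(g$sites$exonic & !is.na(g$sites$gene_id))
  if (!length(ex)) stop("no exonic genic sites available; cannot date")
  gsub_ <- subset_genotypes(g, site_idx = ex)
  het_site <- colSums(gsub_$het_flags) > 0L
  gid <- gsub_$sites$gene_id
  het_per_gene <- tapply(het_site, gid, sum)
  bad_genes <- names(het_per_gene)[het_per_gene > max_het_per_gene]
  keep <- !het_site & !(gid %in% bad_genes)
  if (!any(keep)) stop("no high-confidence exonic sites retained; cannot date")
  gk <- subset_genotypes(gsub_, site_idx = keep)
  sc <- site_counts(gk)
  seg <- which(sc$segregating & sc$n_called >= 1L)
  anc_is_ref <- logical(length(seg))
  derived_count <- integer(length(seg))
  for (k in seq_along(seg)) {
    s <- seg[k]
    x <- sc$n_alt[s]
    n <- sc$n_called[s]
    # majority allele is ancestral; ties -> reference
    anc_is_ref[k] <- (n - x) >= x
    derived_count[k] <- if (anc_is_ref[k]) x else n - x
  }
  tab <- data.frame(
    chrom = gk$sites$chrom[seg], pos = gk$sites$pos[seg],
    ref = gk$sites$ref[seg], alt = gk$sites$alt[seg],
    ancestral = ifelse(anc_is_ref, gk$sites$ref[seg], gk$sites$alt[seg]),
    derived_count = derived_count, n_called = sc$n_called[seg],
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, L = nrow(gk$sites), n = length(gk$line_ids),
                 sum_x = sum(derived_count),
                 called_cells = sum(sc$n_called),
                 n_genes_excluded = length(bad_genes)),
            class = "derived_variant_table")
}

#' @export
print.derived_variant_table <- function(x, ...) {
  cat("<derived_variant_table> S =", nrow(x$table), "variants, sum(x) =",
      x$sum_x, "over L =", x$L, "positions in", x$n, "lines\n")
  invisible(x)
}

#' Thomson TMRCA estimate from derived-variant counts
#'
#' `t_hat = sum(x_i) / (n * mu * L)`: the mean number of derived mutations
#' per lineage divided by the per-lineage mutation rate over the locus. The
#' estimator assumes a star-like genealogy (appropriate immediately after a
#' sweep) and tends to underestimate the TMRCA because it omits the initial
#' spread of the focal haplotype.
#'
#' @param x A `derived_variant_table`, or directly the numeric `sum_x`.
#' @param n Number of sampled lines (taken from `x` when available).
#' @param mu Per-site per-generation mutation rate(s); may be a grid.
#' @param L Number of high-confidence positions. When `x` is a
#'   `derived_variant_table` the default is its missing-data-aware effective
#'   length, `called_cells / n` (the mean number of surveyed positions per
#'   line), so missing genotypes do not attenuate the estimate.
#' @return Data frame of class `thomson_estimate`: one row per `mu` with
#'   `sum_x`, `n`, `L`, `mu`, `t_hat` (generations).
#' @export
thomson_age <- function(x, n = NULL, mu, L = NULL) {
  if (inherits(x, "derived_variant_table")) {
    sum_x <- x$sum_x
    if (is.null(n)) n <- x$n
    if (is.null(L)) L <- x$called_cells / x$n
  } else {
    sum_x <- as.numeric(x)
  }
  if (is.null(n) || is.null(L)) stop("`n` and `L` are required")
  if (any(mu <= 0)) stop("mu must be > 0")
  if (L <= 0) stop("L must be > 0")
  if (n < 1) stop("n must be >= 1")
  if (sum_x < 0) stop("sum_x must be >= 0")
  out <- data.frame(sum_x = sum_x, n = n, L = L, mu = mu,
                    t_hat = sum_x / (n * mu * L))
  class(out) <- c("thomson_estimate", "data.frame")
  out
}

# Per-site mismatch indicator among a set of lines: TRUE where at least two
# non-missing calls disagree.
site_mismatch <- function(calls) {
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 > 0L & n0 > 0L
}

#' Shared core segment around a focal position
#'
#' The maximal contiguous span around `focal_pos` over which the given lines
#' are pairwise identical at jointly genotyped SNPs. Segment boundaries are
#' placed at the midpoint between the outermost matching SNP and the first
#' mismatching SNP (the least-biased convention when the true breakpoint is
#' unobserved); where no mismatch is found before the end of the genotyped
#' region, the boundary is the outermost genotyped position.
#'
#' @param g A [genotype_matrix()] (single chromosome, or use `chrom`).
#' @param lines Character vector (>= 2) of line ids.
#' @param focal_pos 1-based focal coordinate.
#' @param chrom Chromosome to use when `g` spans several.
#' @return Object of class `haplotype_segment`: list with `member_lines`,
#'   `chrom`, `start`, `end`, `length_bp` and `n_snps` (matching SNPs
#'   inside). If the lines differ at the SNP nearest the focal position the
#'   segment has `length_bp = 0`.
#' @export
shared_core_segment <- function(g, lines, focal_pos, chrom = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), length(lines) >= 2)
  if (is.null(chrom)) {
    chrom <- unique(g$sites$chrom)
    if (length(chrom) != 1) stop("specify `chrom` for a multi-chromosome panel")
  }
  idx <- which(g$sites$chrom == chrom)
  o <- order(g$sites$pos[idx])
  idx <- idx[o]
  pos <- g$sites$pos[idx]
  if (focal_pos < pos[1] || focal_pos > pos[length(pos)]) {
    stop("focal_pos outside the genotyped coordinate range")
  }
  calls <- g$calls[lines, idx, drop = FALSE]
  mm <- site_mismatch(calls)
  nearest <- which.min(abs(pos - focal_pos))
  zero <- structure(list(member_lines = lines, chrom = chrom,
                         start = as.integer(focal_pos),
                         end = as.integer(focal_pos),
                         length_bp = 0L, n_snps = 0L),
                    class = "haplotype_segment")
  if (mm[nearest]) return(zero)
  # run of matching SNPs containing the nearest SNP
  left <- nearest
  while (left > 1L && !mm[left - 1L]) left <- left - 1L
  right <- nearest
  while (right < length(pos) && !mm[right + 1L]) right <- right + 1L
  start <- if (left == 1L) pos[1] else
    floor((pos[left - 1L] + pos[left]) / 2) + 1L
  end <- if (right == length(pos)) pos[length(pos)] else
    floor((pos[right] + pos[right + 1L]) / 2)
  structure(list(member_lines = lines, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 length_bp = as.integer(end - start + 1L),
                 n_snps = right - left + 1L),
            class = "haplotype_segment")
}

#' @export
print.haplotype_segment <- function(x, ...) {
  cat(sprintf("<haplotype_segment> %s:%d-%d (%.1f kb, %d SNPs, %d lines)\n",
              x$chrom, x$start, x$end, x$length_bp / 1000, x$n_snps,
              length(x$member_lines)))
  invisible(x)
}

#' Greedy assignment of long-range haplotype groups around a focal position
#'
#' Replaces manual haplotype assignment: each group is seeded with the first
#' unassigned line; an unassigned line joins the group when it matches the
#' seed at the `match_snps` nearest jointly genotyped SNPs on each side of
#' `focal_pos`, tolerating at most `max_mismatch` mismatches. Each group's
#' shared segment is then measured with [shared_core_segment()]; groups
#' smaller than `min_group` are reported as singletons.
#'
#' @param g A [genotype_matrix()] of haploid lines.
#' @param region Optional `c(start, end)` restricting the site window.
#' @param focal_pos Focal coordinate (e.g. the swept gene).
#' @param max_mismatch Mismatches tolerated in the matching window; default 0.
#' @param min_group Minimum members for a reported group; default 2.
#' @param match_snps Jointly genotyped SNPs per side that must match; default 5.
#' @param chrom Chromosome when `g` spans several.
#' @return List of class `haplotype_groups`: `groups` (list of member id
#'   vectors), `segments` (list of `haplotype_segment`), `singletons`,
#'   `summary` (data frame: group, n_members, start, end, length_bp),
#'   `mean_length_bp`, `median_length_bp`.
#' @export
assign_haplotype_groups <- function(g, region = NULL, focal_pos,
                                    max_mismatch = 0, min_group = 2,
                                    match_snps = 5, chrom = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(chrom)) {
    chrom <- unique(g$sites$chrom)
    if (length(chrom) != 1) stop("specify `chrom` for a multi-chromosome panel")
  }
  idx <- which(g$sites$chrom == chrom)
  if (!is.null(region)) {
    idx <- idx[g$sites$pos[idx] >= region[1] & g$sites$pos[idx] <= region[2]]
  }
  idx <- idx[order(g$sites$pos[idx])]
  if (length(idx) < 2) stop("too few SNPs in the region")
  pos <- g$sites$pos[idx]
  calls <- g$calls[, idx, drop = FALSE]
  lines <- g$line_ids
  unassigned <- lines
  groups <- list()
  while (length(unassigned)) {
    seed <- unassigned[1]
    members <- seed
    unassigned <- unassigned[-1]
    if (length(unassigned)) {
      joined <- vapply(unassigned, function(cand) {
        matches_seed_window(calls[seed, ], calls[cand, ], pos, focal_pos,
                            match_snps, max_mismatch)
      }, logical(1))
      members <- c(members, unassigned[joined])
      unassigned <- unassigned[!joined]
    }
    groups[[length(groups) + 1L]] <- members
  }
  sizes <- lengths(groups)
  real <- groups[sizes >= min_group]
  singles <- unlist(groups[sizes < min_group])
  segs <- lapply(real, function(m) {
    shared_core_segment(g, m, focal_pos, chrom = chrom)
  })
  lens <- vapply(segs, function(s) as.numeric(s$length_bp), numeric(1))
  summary <- if (length(real)) data.frame(
    group = seq_along(real), n_members = lengths(real),
    start = vapply(segs, function(s) s$start, integer(1)),
    end = vapply(segs, function(s) s$end, integer(1)),
    length_bp = lens
  ) else data.frame(group = integer(), n_members = integer(),
                    start = integer(), end = integer(), length_bp = numeric())
  structure(list(groups = real, segments = segs,
                 singletons = as.character(singles), summary = summary,
                 mean_length_bp = if (length(lens)) mean(lens) else NA_real_,
                 median_length_bp = if (length(lens)) stats::median(lens)
                                    else NA_real_),
            class = "haplotype_groups")
}

matches_seed_window <- function(seed_calls, cand_calls, pos, focal_pos,
                                match_snps, max_mismatch) {
  joint <- which(!is.na(seed_calls) & !is.na(cand_calls))
  if (!length(joint)) return(FALSE)
  left <- joint[pos[joint] <= focal_pos]
  right <- joint[pos[joint] > focal_pos]
  win <- c(utils::tail(left, match_snps), utils::head(right, match_snps))
  if (length(win) < match_snps) return(FALSE)
  sum(seed_calls[win] != cand_calls[win]) <= max_mismatch
}

#' @export
print.haplotype_groups <- function(x, ...) {
  cat("<haplotype_groups>", length(x$groups), "groups,",
      length(x$singletons), "singletons\n")
  if (nrow(x$summary)) {
    cat(sprintf("  mean length %.1f kb, median %.1f kb\n",
                x$mean_length_bp / 1000, x$median_length_bp / 1000))
  }
  invisible(x)
}

#' Sweep age from haplotype length
#'
#' A haplotype unbroken over `length_kb` around the selected site implies
#' roughly one recombination per haplotype since selection began, so the age
#' in generations is the reciprocal of the haplotype's genetic length:
#' `t = 100 * kb_per_cM / length_kb` (100 cM per Morgan). Vectorised over the
#' Cartesian product of lengths and rates to produce age ranges; no averaging
#' across grid points is performed.
#'
#' @param length_kb Haplotype length(s) in kb.
#' @param kb_per_cM Local recombination rate(s) expressed as kb per cM.
#' @return Data frame of class `haplotype_age`: `length_kb`, `kb_per_cM`,
#'   `t` (generations).
#' @export
haplotype_age_from_length <- function(length_kb, kb_per_cM) {
  if (any(length_kb <= 0)) stop("length_kb must be > 0")
  if (any(kb_per_cM <= 0)) stop("kb_per_cM must be > 0")
  grid <- expand.grid(length_kb = length_kb, kb_per_cM = kb_per_cM,
                      KEEP.OUT.ATTRS = FALSE)
  grid$t <- 100 * grid$kb_per_cM / grid$length_kb
  class(grid) <- c("haplotype_age", "data.frame")
  grid
}
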