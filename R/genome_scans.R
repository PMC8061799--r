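# Chromosome-scale outlier machinery: contiguous-gene-block permutation
# tests for per-gene statistics, and read-depth copy-number classification.

#' Contiguous-block permutation test for a per-gene statistic
#'
#' Compares the mean of a focal block of genes against means of `n_perm`
#' randomly placed contiguous windows of the same size along the chromosome
#' (null windows may overlap the focal block unless `exclude_focal`). The
#' p-value uses the add-one convention `p = (1 + #{null <= obs}) / (n_perm +
#' 1)` for the lower side (mirrored for the upper side), so p is always
#' positive. Deterministic given `seed`.
#'
#' @param per_gene_stat Numeric vector of per-gene values ordered along the
#'   chromosome (map order). `NA`s are ignored within window means.
#' @param focal_block Integer indices of the focal genes (must be contiguous).
#' @param block_size Window size in genes; default 8 (must equal the focal
#'   block length).
#' @param n_perm Number of null windows; default 500.
#' @param side `"lower"` (diversity deficit) or `"upper"`.
#' @param seed Optional integer seed.
#' @param exclude_focal Disallow null windows overlapping the focal block;
#'   default FALSE.
#' @return Object of class `block_permutation`: `observed_mean`,
#'   `null_means`, `p_value`, `side`, `focal_genes`, `n_perm`.
#' @export
block_permutation_test <- function(per_gene_stat, focal_block, block_size = 8,
                                   n_perm = 500, side = c("lower", "upper"),
                                   seed = NULL, exclude_focal = FALSE) {
  side <- match.arg(side)
  G <- length(per_gene_stat)
  if (block_size > G) stop("block_size exceeds the number of genes")
  focal_block <- sort(as.integer(focal_block))
  if (length(focal_block) != block_size ||
      !all(diff(focal_block) == 1L)) {
    stop("focal_block must be ", block_size, " contiguous gene indices")
  }
  if (!is.null(seed)) set.seed(seed)
  n_starts <- G - block_size + 1L
  starts <- sample.int(n_starts, n_perm, replace = TRUE)
  if (exclude_focal) {
    overlaps <- function(s) s <= focal_block[block_size] &
      (s + block_size - 1L) >= focal_block[1]
    bad <- overlaps(starts)
    guard <- 0L
    while (any(bad)) {
      starts[bad] <- sample.int(n_starts, sum(bad), replace = TRUE)
      bad <- overlaps(starts)
      guard <- guard + 1L
      if (guard > 1000L) stop("cannot place non-overlapping null windows")
    }
  }
  observed <- mean(per_gene_stat[focal_block], na.rm = TRUE)
  null_means <- vapply(starts, function(s) {
    mean(per_gene_stat[s:(s + block_size - 1L)], na.rm = TRUE)
  }, numeric(1))
  p <- if (side == "lower") {
    (1 + sum(null_means <= observed)) / (n_perm + 1)
  } else {
    (1 + sum(null_means >= observed)) / (n_perm + 1)
  }
  structure(list(observed_mean = observed, null_means = null_means,
                 p_value = p, side = toupper(side),
                 focal_genes = focal_block, n_perm = n_perm),
            class = "block_permutation")
}

#' @export
print.block_permutation <- function(x, ...) {
  cat(sprintf(
    "<block_permutation> observed mean %.5g, %s-side p = %.4g (N = %d)\n",
    x$observed_mean, tolower(x$side), x$p_value, x$n_perm))
  invisible(x)
}

#' Standardize read depth by line-wise chromosome medians
#'
#' Each depth cell is divided by its line's chromosome-wide median exonic
#' depth, then averaged per gene, giving a per-gene per-line mean
#' standardized depth centred at 1 for single-copy sequence. Lines whose
#' median depth on a chromosome is 0 are excluded with a warning.
#'
#' @param d A [depth_matrix()] whose sites carry `gene_id`.
#' @return Numeric matrix lines x genes of mean standardized depths, with an
#'   `excluded_lines` attribute.
#' @export
standardize_depth <- function(d) {
  stopifnot(inherits(d, "depth_matrix"))
  if (is.null(d$sites$gene_id)) stop("depth sites must carry gene_id")
  genes <- unique(d$sites$gene_id)
  out <- matrix(NA_real_, length(d$line_ids), length(genes),
                dimnames = list(d$line_ids, genes))
  excluded <- character()
  for (ch in unique(d$sites$chrom)) {
    cs <- which(d$sites$chrom == ch)
    med <- apply(d$depth[, cs, drop = FALSE], 1, stats::median, na.rm = TRUE)
    zero <- med == 0 | is.na(med)
    if (any(zero)) {
      excluded <- union(excluded, d$line_ids[zero])
      warning("line(s) with zero median depth on ", ch, " excluded: ",
              paste(d$line_ids[zero], collapse = ", "))
    }
    std <- sweep(d$depth[, cs, drop = FALSE], 1, med, "/")
    std[zero, ] <- NA_real_
    gid <- d$sites$gene_id[cs]
    for (gg in unique(gid)) {
      out[, gg] <- rowMeans(std[, gid == gg, drop = FALSE], na.rm = TRUE)
    }
  }
  attr(out, "excluded_lines") <- excluded
  out
}

#' Classify genes by between-class coverage ratio
#'
#' Genes whose focal-class (D) mean standardized depth falls outside
#' `[d_exclude_lo, d_exclude_hi]` are flagged `EXCLUDED` (likely
#' misassembled or repetitive). For the rest, the D-minus / D coverage
#' ratio is binned: `[0, 0.25]` `DELETED`, `(0.25, 1.75)` `NORMAL`, and
#' `>= 1.75` `DUPLICATED` (the display bins stop at 2.0 only because the
#' plotted track is capped; larger ratios are still duplications).
#'
#' @param std Matrix of per-gene per-line standardized depths (from
#'   [standardize_depth()]).
#' @param panel A `line_panel` data frame assigning `D` / `D_MINUS` classes.
#' @param d_exclude_lo,d_exclude_hi Exclusion bounds on the D-class mean;
#'   defaults 0.5 and 3.0.
#' @return Data frame of class `gene_coverage`: `gene_id`, `mean_std_d`,
#'   `mean_std_dminus`, `ratio`, `category`.
#' @export
classify_coverage_ratio <- function(std, panel, d_exclude_lo = 0.5,
                                    d_exclude_hi = 3.0) {
  d_lines <- intersect(panel$line_id[panel$class == "D"], rownames(std))
  dm_lines <- intersect(panel$line_id[panel$class == "D_MINUS"],
                        rownames(std))
  if (!length(d_lines) || !length(dm_lines)) {
    stop("both D and D_MINUS classes must be represented")
  }
  mean_d <- colMeans(std[d_lines, , drop = FALSE], na.rm = TRUE)
  mean_dm <- colMeans(std[dm_lines, , drop = FALSE], na.rm = TRUE)
  excluded <- mean_d < d_exclude_lo | mean_d > d_exclude_hi
  stopifnot(all(mean_d[!excluded] > 0))
  ratio <- ifelse(excluded, NA_real_, mean_dm / mean_d)
  category <- ifelse(excluded, "EXCLUDED",
              ifelse(ratio <= 0.25, "DELETED",
              ifelse(ratio >= 1.75, "DUPLICATED", "NORMAL")))
  out <- data.frame(gene_id = colnames(std), mean_std_d = mean_d,
                    mean_std_dminus = mean_dm, ratio = ratio,
                    category = category, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("gene_coverage", "data.frame")
  out
}
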