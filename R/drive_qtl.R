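# Female drive strength from selfed-progeny counts, and a Haley-Knott-style
# LOD scan for unlinked modifiers with the drive locus as a binary cofactor.

#' Assemble F2 records for the drive-modifier scan
#'
#' @param f2_id Character vector of F2 identifiers.
#' @param mdl11 Drive-locus genotype per F2: `"DD_MINUS"` or `"Dd"`.
#' @param marker_probs 3-d array `n_f2 x n_marker x 3` of genotype
#'   probabilities, third dimension ordered `GG`, `NG`, `NN`.
#' @param marker_map Data frame `marker`, `chrom`, `cM` (one row per marker,
#'   in scan order).
#' @param f3_counts Integer matrix `n_f2 x 3`: selfed-progeny genotype counts
#'   `n_DD`, `n_Dhet`, `n_other`.
#' @return Object of class `f2_records`.
#' @export
f2_records <- function(f2_id, mdl11, marker_probs, marker_map, f3_counts) {
  f2_id <- as.character(f2_id)
  n <- length(f2_id)
  if (anyDuplicated(f2_id)) stop("f2_id values must be unique")
  if (!all(mdl11 %in% c("DD_MINUS", "Dd"))) {
    stop("mdl11 must be DD_MINUS or Dd")
  }
  stopifnot(length(mdl11) == n)
  if (length(dim(marker_probs)) != 3 || dim(marker_probs)[1] != n ||
      dim(marker_probs)[3] != 3) {
    stop("marker_probs must be an n_f2 x n_marker x 3 array")
  }
  if (nrow(marker_map) != dim(marker_probs)[2]) {
    stop("marker_map rows must match marker_probs markers")
  }
  sums <- apply(marker_probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("genotype probabilities must sum to 1 per marker")
  }
  f3_counts <- as.matrix(f3_counts)
  stopifnot(nrow(f3_counts) == n, ncol(f3_counts) == 3)
  if (any(f3_counts < 0)) stop("F3 counts must be non-negative")
  structure(list(f2_id = f2_id, mdl11 = mdl11, marker_probs = marker_probs,
                 marker_map = as.data.frame(marker_map),
                 f3_counts = f3_counts),
            class = "f2_records")
}

#' @export
print.f2_records <- function(x, ...) {
  cat("<f2_records>", length(x$f2_id), "F2s x", nrow(x$marker_map),
      "markers;", sum(x$mdl11 == "Dd"), "Dd /", sum(x$mdl11 == "DD_MINUS"),
      "DD_MINUS\n")
  invisible(x)
}

#' Estimate female drive strength from selfed-progeny genotype counts
#'
#' With Mendelian transmission through pollen (`m = 0.5` by assumption), the
#' frequency of the driven allele among progeny alleles is `p = (f + m) / 2`,
#' where `f` is the female transmission rate. The method-of-moments inversion
#' of the allele-frequency estimate `p_hat = (2*n_DD + n_Dhet) / (2*n_total)`
#' gives `f_hat = 2*p_hat - m`, clipped to `[0, 1]`.
#'
#' @param f3_counts Length-3 vector `(n_DD, n_Dhet, n_other)` or a matrix
#'   with one such row per F2.
#' @param male_transmission Assumed male transmission of the driven allele;
#'   default 0.5 (no distortion through pollen).
#' @return Estimated female transmission rate(s) in `[0, 1]`; `NA` when a
#'   family has no progeny.
#' @export
estimate_drive_strength <- function(f3_counts, male_transmission = 0.5) {
  m <- if (is.matrix(f3_counts)) f3_counts else matrix(f3_counts, nrow = 1)
  if (ncol(m) != 3) stop("f3_counts must have three genotype classes")
  if (any(m < 0)) stop("F3 counts must be non-negative")
  tot <- rowSums(m)
  p_hat <- (2 * m[, 1] + m[, 2]) / (2 * tot)
  f_hat <- pmin(pmax(2 * p_hat - male_transmission, 0), 1)
  f_hat[tot == 0] <- NA_real_
  unname(f_hat)
}

#' Harden genotype-probability triples into calls
#'
#' A genotype is called only when its probability strictly exceeds the
#' threshold; otherwise the call is missing.
#'
#' @param marker_probs Numeric matrix `n x 3` (columns `GG`, `NG`, `NN`), a
#'   length-3 vector, or a 3-d `n x m x 3` array.
#' @param threshold Calling threshold; default 0.8 (strict `>`).
#' @return Character calls (`"GG"`, `"NG"`, `"NN"` or `NA`), shaped to match
#'   the input.
#' @export
harden_genotype_calls <- function(marker_probs, threshold = 0.8) {
  classes <- c("GG", "NG", "NN")
  if (is.array(marker_probs) && length(dim(marker_probs)) == 3) {
    dm <- dim(marker_probs)
    flat <- matrix(marker_probs, ncol = 3)
    calls <- harden_genotype_calls(flat, threshold)
    return(matrix(calls, dm[1], dm[2]))
  }
  m <- if (is.matrix(marker_probs)) marker_probs else
    matrix(marker_probs, nrow = 1)
  if (ncol(m) != 3) stop("probability triples expected")
  if (any(abs(rowSums(m) - 1) > 1e-6)) {
    stop("genotype probabilities must sum to 1")
  }
  best <- max.col(m, ties.method = "first")
  calls <- classes[best]
  calls[m[cbind(seq_len(nrow(m)), best)] <= threshold] <- NA_character_
  if (!is.matrix(marker_probs) && is.null(dim(marker_probs))) calls[1]
  else calls
}

#' LOD scan for drive modifiers with the drive locus as binary cofactor
#'
#' Regression-on-genotype-probabilities (Haley-Knott style) at observed
#' markers: the phenotype (estimated female drive strength) is regressed on
#' the expected driven-species allele dosage `2*P(GG) + P(NG)`, with the
#' binary drive-locus genotype in both the null and the full model, so the
#' LOD measures the marker effect beyond the drive locus:
#' `LOD = (n/2) * log10(RSS0 / RSS1)`. F2s whose phenotype rests on fewer
#' than `min_family` progeny, or with more than `max_missing` missing
#' hardened marker calls, are dropped before the scan.
#'
#' @param f2 An [f2_records()] object.
#' @param min_family Minimum F3 progeny per F2; default 12.
#' @param max_missing Maximum fraction of missing hardened calls; default 0.5.
#' @param cofactor Include the drive-locus cofactor; default TRUE.
#' @param smooth_window Window for the smoothed trace; default 4 markers.
#' @param call_threshold Hardening threshold for the missing-data filter;
#'   default 0.8.
#' @return Data frame of class `lod_profile`: `marker`, `chrom`, `cM`,
#'   `lod`, `smoothed`, `flat` (TRUE where the marker had no dosage
#'   variation), with attributes `n_used` and `cofactor`.
#' @export
lod_scan <- function(f2, min_family = 12, max_missing = 0.5, cofactor = TRUE,
                     smooth_window = 4, call_threshold = 0.8) {
  stopifnot(inherits(f2, "f2_records"))
  pheno <- estimate_drive_strength(f2$f3_counts)
  n_prog <- rowSums(f2$f3_counts)
  calls <- harden_genotype_calls(f2$marker_probs, call_threshold)
  miss_frac <- rowMeans(is.na(calls))
  keep <- !is.na(pheno) & n_prog >= min_family & miss_frac <= max_missing
  n <- sum(keep)
  if (n < 20) stop("fewer than 20 eligible F2s after filtering (", n, ")")
  y <- pheno[keep]
  pr <- f2$marker_probs[keep, , , drop = FALSE]
  dosage <- matrix(2 * pr[, , 1] + pr[, , 2], nrow = n)
  x0 <- if (cofactor) as.numeric(f2$mdl11[keep] == "Dd") else NULL
  X0 <- cbind(1, x0)
  rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
  m <- ncol(dosage)
  lod <- numeric(m)
  flat <- logical(m)
  if (rss0 > 1e-12) {  # a phenotype fully explained by the null scores 0
    for (j in seq_len(m)) {
      dj <- dosage[, j]
      if (stats::var(dj) < 1e-12) {
        flat[j] <- TRUE
        next
      }
      fit <- stats::lm.fit(cbind(X0, dj), y)
      rss1 <- sum(fit$residuals^2)
      lod[j] <- max(0, (n / 2) * log10(rss0 / rss1))
    }
  }
  out <- data.frame(marker = f2$marker_map$marker, chrom = f2$marker_map$chrom,
                    cM = f2$marker_map$cM, lod = lod,
                    smoothed = smooth_lod(lod, smooth_window), flat = flat,
                    stringsAsFactors = FALSE)
  attr(out, "n_used") <- n
  attr(out, "cofactor") <- cofactor
  class(out) <- c("lod_profile", "data.frame")
  out
}

#' Moving-average smoothing of a LOD trace
#'
#' Centred window: position `i` averages markers
#' `i - floor((window-1)/2)` through `i + floor(window/2)`, truncated to the
#' available trace at the edges. `window = 1` is the identity; a window
#' longer than the trace returns the global mean everywhere.
#'
#' @param lod Numeric trace.
#' @param window Window size in markers; default 4.
#' @return Smoothed trace of the same length.
#' @export
smooth_lod <- function(lod, window = 4) {
  if (window < 1) stop("window must be >= 1")
  n <- length(lod)
  lo <- pmax(1L, seq_len(n) - floor((window - 1) / 2))
  hi <- pmin(n, seq_len(n) + floor(window / 2))
  vapply(seq_len(n), function(i) mean(lod[lo[i]:hi[i]]), numeric(1))
}

#' Two-way ANOVA of drive strength on modifier and drive-locus genotypes
#'
#' Type-II sums of squares (appropriate for the unbalanced genotype counts of
#' an intercross) for the two factors and their interaction. If empty cells
#' make the interaction inestimable, the additive model is fitted and the
#' interaction row is flagged `NA`.
#'
#' @param pheno Numeric phenotype (e.g. estimated female drive strength).
#' @param factor_a First factor (e.g. four modifier-locus genotypes).
#' @param factor_b Second factor (e.g. two drive-locus genotypes).
#' @return Data frame of class `anova_table`: `term`, `sum_sq`, `df`,
#'   `f_value`, `p_value` (terms: factor_a, factor_b, interaction,
#'   Residuals).
#' @export
two_way_anova <- function(pheno, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("both factors need at least two levels")
  }
  dat <- data.frame(y = pheno, a = a, b = b)
  full <- stats::lm(y ~ a * b, data = dat)
  interaction_ok <- full$df.residual >= 1 && !anyNA(stats::coef(full))
  if (interaction_ok && sum(stats::residuals(full)^2) < 1e-20) {
    # degenerate (noise-free) data: car::Anova refuses a zero residual sum
    # of squares, so take the Type-II decomposition from nested fits
    rss <- function(f) sum(stats::residuals(stats::lm(f, dat))^2)
    r_full <- rss(y ~ a * b); r_ab <- rss(y ~ a + b)
    ss <- c(rss(y ~ b) - r_ab, rss(y ~ a) - r_ab, r_ab - r_full)
    df <- c(nlevels(a) - 1, nlevels(b) - 1,
            (nlevels(a) - 1) * (nlevels(b) - 1))
    out <- data.frame(
      term = c("factor_a", "factor_b", "interaction", "Residuals"),
      sum_sq = c(ss, r_full), df = c(df, full$df.residual),
      f_value = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
    class(out) <- c("anova_table", "data.frame")
    return(out)
  }
  if (interaction_ok) {
    tab <- car::Anova(full, type = 2)
    terms <- c("a", "b", "a:b", "Residuals")
  } else {
    add <- stats::lm(y ~ a + b, data = dat)
    tab <- car::Anova(add, type = 2)
    terms <- c("a", "b", "Residuals")
  }
  m <- match(terms, rownames(tab))
  out <- data.frame(
    term = c("factor_a", "factor_b", "interaction", "Residuals"),
    sum_sq = NA_real_, df = NA_real_, f_value = NA_real_, p_value = NA_real_,
    stringsAsFactors = FALSE
  )
  src <- data.frame(term = sub("^a:b$", "interaction",
                               sub("^a$", "factor_a",
                                   sub("^b$", "factor_b", terms))),
                    sum_sq = tab[m, "Sum Sq"], df = tab[m, "Df"],
                    f_value = tab[m, "F value"], p_value = tab[m, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  out[match(src$term, out$term), -1] <- src[, -1]
  class(out) <- c("anova_table", "data.frame")
  out
}
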