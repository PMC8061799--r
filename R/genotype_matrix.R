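#' Construct a haploid genotype matrix
#'
#' Container for a panel of effectively haploid lines typed at biallelic SNPs.
#' Calls are coded `0` (reference allele), `1` (alternate allele) or `NA`
#' (missing). Inbred lines are represented haploid: a homozygous diploid call
#' collapses to a single allele code, while an originally heterozygous diploid
#' call is stored as `NA` with the corresponding `het_flags` cell set, so that
#' downstream site filters can still act on heterozygosity.
#'
#' @param calls Integer matrix, lines x sites, values in `{0L, 1L, NA}`.
#' @param sites Data frame with one row per site and columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `gene_id` (may be `NA`) and `exonic` (logical).
#' @param het_flags Logical matrix, same dimensions as `calls`, marking cells
#'   whose original diploid genotype was heterozygous. Defaults to all `FALSE`.
#' @param line_ids Character vector of line identifiers; defaults to
#'   `rownames(calls)`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `line_ids`, `sites`, `calls` and `het_flags`.
#' @export
genotype_matrix <- function(calls, sites, het_flags = NULL,
                            line_ids = rownames(calls)) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  if (is.null(line_ids)) line_ids <- paste0("line", seq_len(nrow(calls)))
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) stop("line ids must be unique")
  if (length(line_ids) != nrow(calls)) {
    stop("length(line_ids) must equal nrow(calls)")
  }
  if (is.null(het_flags)) {
    het_flags <- matrix(FALSE, nrow(calls), ncol(calls))
  }
  if (!identical(dim(het_flags), dim(calls))) {
    stop("`het_flags` must have the same dimensions as `calls`")
  }
  sites <- validate_sites(sites, n = ncol(calls))
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stop("calls must be 0, 1 or NA")
  }
  dimnames(calls) <- list(line_ids, NULL)
  dimnames(het_flags) <- list(line_ids, NULL)
  structure(
    list(line_ids = line_ids, sites = sites, calls = calls,
         het_flags = het_flags),
    class = "genotype_matrix"
  )
}

validate_sites <- function(sites, n) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(needed, names(sites))
  if (length(miss)) stop("sites lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(sites) != n) stop("nrow(sites) must equal ncol(calls)")
  if (is.null(sites$gene_id)) sites$gene_id <- NA_character_
  if (is.null(sites$exonic)) sites$exonic <- TRUE
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L)) stop("site positions must be >= 1")
  rownames(sites) <- NULL
  sites
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$line_ids), " lines x ",
      nrow(x$sites), " sites\n", sep = "")
  nm <- sum(!is.na(x$calls))
  cat("  non-missing calls: ", nm, " (",
      round(100 * nm / length(x$calls), 1), "%), het-flagged cells: ",
      sum(x$het_flags), "\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$sites$chrom), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by lines and/or sites
#'
#' @param x A [genotype_matrix()].
#' @param lines Line identifiers or indices (default: all).
#' @param site_idx Site indices or logical mask (default: all).
#' @return A `genotype_matrix` restricted to the requested lines and sites.
#' @export
subset_genotypes <- function(x, lines = NULL, site_idx = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  li <- if (is.null(lines)) seq_along(x$line_ids) else {
    if (is.character(lines)) {
      idx <- match(lines, x$line_ids)
      if (anyNA(idx)) stop("unknown line id(s): ",
                           paste(lines[is.na(idx)], collapse = ", "))
      idx
    } else lines
  }
  si <- if (is.null(site_idx)) seq_len(nrow(x$sites)) else {
    if (is.logical(site_idx)) which(site_idx) else site_idx
  }
  genotype_matrix(
    calls = x$calls[li, si, drop = FALSE],
    sites = x$sites[si, , drop = FALSE],
    het_flags = x$het_flags[li, si, drop = FALSE],
    line_ids = x$line_ids[li]
  )
}

#' Per-site summaries of a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @return Data frame with per-site counts: `n_called` (non-missing lines),
#'   `n_alt` (alternate-allele carriers) and `segregating`.
#' @export
site_counts <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  n_called <- colSums(!is.na(x$calls))
  n_alt <- colSums(x$calls == 1L, na.rm = TRUE)
  data.frame(
    n_called = n_called,
    n_alt = n_alt,
    segregating = n_alt > 0L & n_alt < n_called
  )
}
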