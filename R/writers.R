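# Plain-text writers emitting the exact dialects the core_io readers consume,
# so generated panels round-trip losslessly.

#' Write a genotype matrix as VCF v4.2
#'
#' Calls are emitted as homozygous diploid genotypes (`0/0`, `1/1`); a cell
#' flagged heterozygous is written `0/1`; missing is `./.`. Per-sample depth
#' (`DP`) is written so that [read_panel()] reproduces the matrix: called and
#' het cells get `depth_called`, missing cells get 0.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file.
#' @param depth_called Depth emitted for non-missing cells; default 10.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(g, path, depth_called = 10L) {
  stopifnot(inherits(g, "genotype_matrix"))
  s <- g$sites
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$line_ids), collapse = "\t")
  )
  gt <- matrix("./.:0", nrow(s), length(g$line_ids))
  dpstr <- paste0(":", depth_called)
  tc <- t(g$calls)
  th <- t(g$het_flags)
  gt[!is.na(tc) & tc == 0L] <- paste0("0/0", dpstr)
  gt[!is.na(tc) & tc == 1L] <- paste0("1/1", dpstr)
  gt[th] <- paste0("0/1", dpstr)
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT:DP",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a gene annotation table
#' @param ann A `gene_annotation`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  out <- ann[, c("gene_id", "chrom", "start", "end", "map_order", "region")]
  out$exons <- vapply(ann$exon_list, function(ex) {
    paste(paste0(ex[, 1], "-", ex[, 2]), collapse = ";")
  }, character(1))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a depth matrix table
#' @param d A [depth_matrix()].
#' @param path Output TSV (site rows, line columns).
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(d, path) {
  stopifnot(inherits(d, "depth_matrix"))
  out <- cbind(d$sites[, c("chrom", "pos")],
               as.data.frame(t(d$depth), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a line panel table
#' @param lp A `line_panel` data frame.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_line_panel_tsv <- function(lp, path) {
  utils::write.table(as.data.frame(lp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
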