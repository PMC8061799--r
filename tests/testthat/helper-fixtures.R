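# In-code fixture builders shared across test files.

# genotype matrix from a lines x sites integer matrix on one chromosome,
# with evenly spaced positions and a single-gene (or per-gene) assignment
make_gm <- function(calls, gene_id = "g1", pos = NULL, chrom = "chr1",
                    het_flags = NULL, exonic = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n_sites <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(n_sites) * 100L
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      gene_id = rep(gene_id, length.out = n_sites),
                      exonic = rep(exonic, length.out = n_sites),
                      stringsAsFactors = FALSE)
  genotype_matrix(calls, sites, het_flags = het_flags)
}

# annotation covering `n_genes` consecutive spans on one chromosome
make_annotation <- function(n_genes = 1, span = 10000L, chrom = "chr1",
                            region = "OTHER") {
  start <- (seq_len(n_genes) - 1L) * span + 1L
  as_gene_annotation(data.frame(
    gene_id = paste0("g", seq_len(n_genes)), chrom = chrom, start = start,
    end = start + span - 1L,
    exons = paste0(start, "-", start + span - 1L),
    map_order = seq_len(n_genes),
    region = rep(region, length.out = n_genes),
    stringsAsFactors = FALSE
  ))
}

# write a small VCF from explicit record fields; gts is a list of per-sample
# "GT:DP" strings per record
make_vcf <- function(path, chrom, pos, ref, alt, gts, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".",
            "GT:DP", gts[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# random genotype matrix with missing data for oracle-equivalence sweeps
random_gm <- function(n_lines, n_sites, miss = 0.15, gene_id = "g1") {
  calls <- matrix(rbinom(n_lines * n_sites, 1, runif(1, 0.2, 0.8)),
                  n_lines, n_sites)
  calls[runif(length(calls)) < miss] <- NA
  make_gm(calls, gene_id = gene_id)
}
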