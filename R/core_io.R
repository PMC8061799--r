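#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id`, `chrom`, `start`, `end`, `exons`
#' (1-based inclusive intervals encoded `start-end;start-end`), `map_order`
#' (integer rank along the re-ordered chromosome) and `region` (one of
#' `MDL11`, `FLANKING`, `OTHER`).
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `gene_annotation`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  as_gene_annotation(ann)
}

#' Validate and classify a gene annotation data frame
#'
#' @param ann Data frame with the columns described in [read_annotation()].
#'   `exons` may alternatively be a list column of 2-column matrices.
#' @return The validated data frame with class `gene_annotation` and a parsed
#'   `exon_list` column.
#' @export
as_gene_annotation <- function(ann) {
  needed <- c("gene_id", "chrom", "start", "end", "map_order", "region")
  miss <- setdiff(needed, names(ann))
  if (length(miss)) stop("annotation lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id)) stop("gene_id values must be unique")
  if (any(ann$start > ann$end)) stop("gene start must be <= end")
  if (!all(ann$region %in% c("MDL11", "FLANKING", "OTHER"))) {
    stop("region must be one of MDL11, FLANKING, OTHER")
  }
  for (ch in unique(ann$chrom)) {
    mo <- ann$map_order[ann$chrom == ch]
    if (anyDuplicated(mo)) stop("map_order must be unique within chromosome ", ch)
  }
  if (is.null(ann$exon_list)) {
    if (is.null(ann$exons)) {
      ann$exon_list <- Map(function(s, e) cbind(start = s, end = e),
                           ann$start, ann$end)
    } else {
      ann$exon_list <- lapply(ann$exons, parse_exon_string)
    }
  }
  for (i in seq_len(nrow(ann))) {
    ex <- ann$exon_list[[i]]
    if (any(ex[, 1] < ann$start[i]) || any(ex[, 2] > ann$end[i])) {
      stop("exons of gene ", ann$gene_id[i], " extend outside the gene span")
    }
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

parse_exon_string <- function(s) {
  if (is.na(s) || !nzchar(s)) return(cbind(start = integer(), end = integer()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p[1:2])))
  colnames(m) <- c("start", "end")
  m
}

#' Import a gene annotation from a GFF3 file
#'
#' Convenience wrapper building the package's annotation table from `gene` and
#' `exon` records of a GFF3 file. `map_order` is assigned by start coordinate
#' within each chromosome and `region` defaults to `OTHER` unless gene ids are
#' supplied.
#'
#' @param path GFF3 file.
#' @param mdl11_genes,flanking_genes Optional character vectors of gene ids to
#'   label `MDL11` / `FLANKING`.
#' @return A `gene_annotation` data frame.
#' @export
annotation_from_gff3 <- function(path, mdl11_genes = NULL,
                                 flanking_genes = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("annotation_from_gff3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  genes <- gr[ty == "gene"]
  exons <- gr[ty == "exon"]
  gid <- as.character(genes$ID)
  ex_parent <- sub("^.*:", "", as.character(unlist(exons$Parent)))
  ann <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    map_order = NA_integer_,
    region = "OTHER",
    stringsAsFactors = FALSE
  )
  ann$exon_list <- lapply(gid, function(g) {
    ex <- exons[ex_parent == g]
    if (!length(ex)) return(cbind(start = ann$start[match(g, gid)],
                                  end = ann$end[match(g, gid)]))
    cbind(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex))
  })
  for (ch in unique(ann$chrom)) {
    k <- ann$chrom == ch
    ann$map_order[k] <- rank(ann$start[k], ties.method = "first")
  }
  if (!is.null(mdl11_genes)) ann$region[ann$gene_id %in% mdl11_genes] <- "MDL11"
  if (!is.null(flanking_genes)) {
    ann$region[ann$gene_id %in% flanking_genes] <- "FLANKING"
  }
  as_gene_annotation(ann)
}

#' Read the line panel table
#'
#' TSV with columns `line_id`, `class` (one of `D`, `D_MINUS`, `UNKNOWN`) and
#' `population`.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `line_panel`.
#' @export
read_line_panel <- function(path) {
  lp <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  as_line_panel(lp)
}

#' @rdname read_line_panel
#' @param lp Data frame with `line_id`, `class`, `population`.
#' @export
as_line_panel <- function(lp) {
  miss <- setdiff(c("line_id", "class", "population"), names(lp))
  if (length(miss)) stop("line panel lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(lp$line_id)) stop("line_id values must be unique")
  if (!all(lp$class %in% c("D", "D_MINUS", "UNKNOWN"))) {
    stop("line class must be one of D, D_MINUS, UNKNOWN")
  }
  class(lp) <- c("line_panel", "data.frame")
  lp
}

# Assign each position to a gene (NA when intergenic) and flag exonic
# positions. Genes are assumed non-overlapping within a chromosome.
locate_in_genes <- function(chrom, pos, annotation) {
  gene_id <- rep(NA_character_, length(pos))
  exonic <- rep(FALSE, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    g <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    o <- order(g$start)
    g <- g[o, , drop = FALSE]
    idx <- findInterval(pos[sel], g$start)
    ok <- idx >= 1L & pos[sel] <= g$end[pmax(idx, 1L)]
    hit <- sel[ok]
    gi <- idx[ok]
    gene_id[hit] <- g$gene_id[gi]
    for (j in seq_along(hit)) {
      ex <- g$exon_list[[gi[j]]]
      exonic[hit[j]] <- any(pos[hit[j]] >= ex[, 1] & pos[hit[j]] <= ex[, 2])
    }
  }
  data.frame(gene_id = gene_id, exonic = exonic, stringsAsFactors = FALSE)
}

#' Read an inbred panel from a VCF file
#'
#' Retains biallelic SNPs inside annotated genes; drops indels and
#' multi-allelic records (their counts are reported in the attached filter
#' log). Genotypes supported by fewer than `min_depth` reads are converted to
#' missing. Originally heterozygous calls (at depth `>= min_depth`) are stored
#' as missing with the `het_flags` cell set, so the inbred site filters can
#' remove heterozygous sites.
#'
#' @param vcf_source Path to a VCF (v4.x) file with `GT` and per-sample `DP`.
#' @param annotation A `gene_annotation` (see [read_annotation()]).
#' @param min_depth Minimum per-genotype read depth; default 3.
#' @return A [genotype_matrix()] with a `filter_log` attribute (counts of
#'   dropped indel / multi-allelic / intergenic records and depth-masked
#'   genotype cells).
#' @export
read_panel <- function(vcf_source, annotation, min_depth = 3) {
  stopifnot(inherits(annotation, "gene_annotation"))
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_source, verbose = FALSE),
    error = function(e) stop("malformed VCF (", vcf_source, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no records")
  fix$POS <- as.integer(fix$POS)
  if (anyNA(fix$POS)) {
    bad <- which(is.na(fix$POS))[1]
    stop("malformed VCF record at index ", bad, " (non-numeric POS)")
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  indel <- !multi & (nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L |
                       fix$ALT == "." | is.na(fix$ALT))
  snp <- !multi & !indel

  loc <- locate_in_genes(fix$CHROM, fix$POS, annotation)
  genic <- !is.na(loc$gene_id)
  keep <- which(snp & genic)
  log <- list(
    n_records = nrow(fix),
    n_multiallelic = sum(multi),
    n_indel = sum(indel),
    n_intergenic = sum(snp & !genic),
    n_kept = length(keep)
  )
  if (!length(keep)) stop("no biallelic genic SNPs retained from VCF")

  gt <- vcfR::extract.gt(vcf)[keep, , drop = FALSE]
  dp <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  )[keep, , drop = FALSE]

  alleles <- gsub("[|/]", "", gt)
  het <- !is.na(gt) & nchar(alleles) == 2L &
    substr(alleles, 1, 1) != substr(alleles, 2, 2)
  call1 <- substr(alleles, 1, 1)
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt))
  calls[!is.na(gt) & !het & call1 == "0"] <- 0L
  calls[!is.na(gt) & !het & call1 == "1"] <- 1L

  if (all(is.na(dp))) {
    warning("VCF carries no per-sample DP; depth filter not applied")
    mask <- matrix(FALSE, nrow(gt), ncol(gt))
    low <- mask
  } else {
    low <- !is.na(dp) & dp < min_depth
    mask <- low | (is.na(dp) & !is.na(gt))
  }
  log$n_low_depth_cells <- sum(low & !is.na(calls) | low & het)
  calls[mask] <- NA_integer_
  het[mask] <- FALSE

  sites <- data.frame(
    chrom = fix$CHROM[keep], pos = fix$POS[keep],
    ref = fix$REF[keep], alt = fix$ALT[keep],
    gene_id = loc$gene_id[keep], exonic = loc$exonic[keep],
    stringsAsFactors = FALSE
  )
  g <- genotype_matrix(t(calls), sites, het_flags = t(het),
                       line_ids = colnames(gt))
  attr(g, "filter_log") <- log
  g
}

#' Apply the inbred-panel site filters
#'
#' First removes every site carrying at least one heterozygous call (inbred
#' lines should be homozygous; residual hets flag paralog collapse or mapping
#' artefacts), then removes sites with fewer than `min_lines` non-missing
#' calls. The order is fixed: het-site removal precedes the call-count filter,
#' so a het call never counts toward `min_lines`.
#'
#' @param g A [genotype_matrix()] with populated `het_flags`.
#' @param min_lines Minimum number of lines with a genotype call; default 10.
#' @return The filtered `genotype_matrix` (site order preserved).
#' @export
apply_inbred_site_filters <- function(g, min_lines = 10) {
  stopifnot(inherits(g, "genotype_matrix"))
  no_het <- colSums(g$het_flags) == 0L
  g2 <- subset_genotypes(g, site_idx = no_het)
  enough <- colSums(!is.na(g2$calls)) >= min_lines
  if (!any(enough)) stop("no sites survive the inbred site filters")
  subset_genotypes(g2, site_idx = enough)
}

#' Apply the per-gene retained-site filter
#'
#' Genes with fewer than `min_sites` retained sites are dropped together with
#' all their sites.
#'
#' @param g A filtered [genotype_matrix()] whose sites carry `gene_id`.
#' @param annotation A `gene_annotation`; every `gene_id` referenced by a site
#'   must be present.
#' @param min_sites Minimum retained sites per gene; default 150.
#' @return List with `genotypes` (the filtered matrix) and `genes` (data frame
#'   `gene_id`, `n_sites`, `kept` for every gene with at least one site).
#' @export
apply_gene_filters <- function(g, annotation, min_sites = 150) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(annotation, "gene_annotation"))
  gid <- g$sites$gene_id
  if (anyNA(gid)) stop("all sites must carry a gene_id")
  unknown <- setdiff(unique(gid), annotation$gene_id)
  if (length(unknown)) {
    stop("site gene_id(s) absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  counts <- table(gid)
  genes <- data.frame(
    gene_id = names(counts),
    n_sites = as.integer(counts),
    stringsAsFactors = FALSE
  )
  genes$kept <- genes$n_sites >= min_sites
  keep_sites <- gid %in% genes$gene_id[genes$kept]
  if (!any(keep_sites)) stop("no genes survive the per-gene site filter")
  list(genotypes = subset_genotypes(g, site_idx = keep_sites), genes = genes)
}

#' Construct a depth matrix
#'
#' @param depth Numeric matrix lines x sites of per-site read depths.
#' @param sites Data frame with `chrom`, `pos` and optionally `gene_id` per
#'   site (exonic positions only).
#' @param line_ids Character vector of line ids; defaults to `rownames(depth)`.
#' @return Object of class `depth_matrix`.
#' @export
depth_matrix <- function(depth, sites, line_ids = rownames(depth)) {
  if (!is.matrix(depth)) stop("`depth` must be a matrix")
  if (any(depth < 0, na.rm = TRUE)) stop("read depths must be non-negative")
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (nrow(sites) != ncol(depth)) stop("nrow(sites) must equal ncol(depth)")
  if (is.null(line_ids)) line_ids <- paste0("line", seq_len(nrow(depth)))
  dimnames(depth) <- list(line_ids, NULL)
  structure(list(line_ids = as.character(line_ids), sites = sites,
                 depth = depth),
            class = "depth_matrix")
}

#' @export
print.depth_matrix <- function(x, ...) {
  cat("<depth_matrix> ", length(x$line_ids), " lines x ", nrow(x$sites),
      " exonic sites\n", sep = "")
  invisible(x)
}

#' Read a per-site read-depth matrix
#'
#' The copy-number path deliberately relaxes the genotype-level filters: no
#' minimum-depth masking is applied and missing data are allowed. Sites are
#' restricted to exonic positions of the annotation; anything else is dropped.
#'
#' @param depth_source TSV with columns `chrom`, `pos`, then one column per
#'   line.
#' @param annotation A `gene_annotation`.
#' @return A [depth_matrix()] whose `sites` carry the assigned `gene_id`.
#' @export
read_depth_matrix <- function(depth_source, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  tab <- utils::read.delim(depth_source, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  if (!all(c("chrom", "pos") %in% names(tab))) {
    stop("depth table must have `chrom` and `pos` columns")
  }
  line_cols <- setdiff(names(tab), c("chrom", "pos"))
  d <- as.matrix(tab[, line_cols, drop = FALSE])
  if (any(d < 0, na.rm = TRUE)) stop("read depths must be non-negative")
  loc <- locate_in_genes(tab$chrom, tab$pos, annotation)
  keep <- !is.na(loc$gene_id) & loc$exonic
  sites <- data.frame(chrom = tab$chrom[keep], pos = tab$pos[keep],
                      gene_id = loc$gene_id[keep], stringsAsFactors = FALSE)
  depth_matrix(t(d[keep, , drop = FALSE]), sites, line_ids = line_cols)
}
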