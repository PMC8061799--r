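# End-to-end orchestration over synthetic inputs: generate a panel, run the
# diversity/dating/scan/QTL stages in dependency order, and leave a manifest
# of artifacts. Stage seeds are derived deterministically from one master
# seed so partial reruns stay reproducible.

# rolling polynomial hash (stable across sessions, no deps)
fnv1a_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stage_header <- function(stage, seed, cfg_hash) {
  sprintf("# centrodrive %s stage=%s seed=%d config=%s",
          as.character(utils::packageVersion("centrodrive")), stage, seed,
          cfg_hash)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles per-stage settings around one master seed. The default panel and
#' cross are scaled-down demonstrations of the full study geometry (fewer
#' genes and sites per gene) so an end-to-end run completes in seconds; pass
#' `panel = list()` to use the full-size panel defaults.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param panel Named list of [panel_sim_config()] overrides.
#' @param cross Named list of [cross_sim_config()] overrides.
#' @param flanks Named list of [simulate_swept_flank_haplotypes()] overrides.
#' @param mu_grid Mutation-rate grid for Thomson dating.
#' @param kb_per_cM_grid Recombination-rate grid for haplotype-length dating.
#' @param min_depth,min_lines,min_sites Filter thresholds (see
#'   [read_panel()], [apply_inbred_site_filters()], [apply_gene_filters()]).
#' @param block_size,n_perm Block-permutation settings.
#' @param n_boot Bootstrap replicates for region summaries.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            panel = list(sites_per_gene = 200,
                                         n_genes_mdl11 = 40,
                                         n_genes_flank = 80,
                                         n_deleted_genes = 8),
                            cross = list(n_f2 = 130),
                            flanks = list(),
                            mu_grid = c(0.2e-8, 1.5e-8),
                            kb_per_cM_grid = c(150, 1000),
                            min_depth = 3, min_lines = 10, min_sites = 150,
                            block_size = 8, n_perm = 500, n_boot = 1000) {
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_artifacts <- list(
  panel = c("panel.vcf", "annotation.tsv", "depth.tsv", "lines.tsv",
            "panel_truth.tsv"),
  stats = c("gene_stats.tsv", "region_summary.tsv", "gene_pair_ld.tsv"),
  dating = c("thomson.tsv"),
  flanks = c("haplotype_groups.tsv", "haplotype_ages.tsv"),
  scans = c("block_permutation.tsv", "coverage_classes.tsv"),
  qtl = c("drive_phenotypes.tsv", "lod_profile.tsv")
)

stage_requires <- list(
  panel = character(),
  stats = "panel",
  dating = "panel",
  flanks = character(),
  scans = c("panel", "stats"),
  qtl = character()
)

#' Run the analysis pipeline on synthetic inputs
#'
#' Stages run in dependency order: `panel` (generate and write the inbred
#' panel), `stats` (filters + per-gene diversity, divergence, LD, region
#' summaries), `dating` (Thomson dating of the driving class), `flanks`
#' (swept-flank haplotype groups and length-based ages), `scans` (block
#' permutation outlier test and coverage classification) and `qtl` (drive
#' cross + LOD scan). Each output TSV carries a header comment with package
#' version, stage seed and a config hash; `manifest.tsv` lists every
#' artifact. A stage whose upstream artifacts are absent from `out_dir`
#' fails fast naming the missing dependency.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Subset of stages to run (default: all, in order).
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, the manifest data frame (`stage`, `path`).
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("panel", "stats", "dating", "flanks",
                                    "scans", "qtl"),
                         out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  all_stages <- names(pipeline_artifacts)
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stage_seeds <- stats::setNames(sample.int(2^31 - 1, length(all_stages)),
                                 all_stages)
  cfg_hash <- fnv1a_hash(unclass(cfg))
  pth <- function(f) file.path(out_dir, f)
  manifest <- data.frame(stage = character(), path = character(),
                         stringsAsFactors = FALSE)
  note <- function(stage, files) {
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, path = files,
                                  stringsAsFactors = FALSE))
  }
  for (st in stages) {
    for (req in stage_requires[[st]]) {
      missing <- !file.exists(pth(pipeline_artifacts[[req]]))
      if (any(missing)) {
        stop("stage '", st, "' requires artifact(s) from stage '", req,
             "': ", paste(pipeline_artifacts[[req]][missing],
                          collapse = ", "), " not found in ", out_dir)
      }
    }
    hdr <- stage_header(st, stage_seeds[[st]], cfg_hash)
    message("[centrodrive] stage ", st)
    switch(st,
      panel = {
        pcfg <- do.call(panel_sim_config,
                        c(cfg$panel, list(seed = stage_seeds[[st]])))
        sim <- simulate_inbred_panel(pcfg)
        write_panel_vcf(sim$genotypes, pth("panel.vcf"))
        write_annotation_tsv(sim$annotation, pth("annotation.tsv"))
        write_depth_tsv(sim$depth, pth("depth.tsv"))
        write_line_panel_tsv(sim$panel, pth("lines.tsv"))
        write_tsv_with_header(
          data.frame(key = c("sweep_age", "mu", "n_d", "deleted_genes"),
                     value = c(pcfg$sweep_age, pcfg$mu, sim$truth$n_d,
                               paste(range(sim$truth$deleted_genes),
                                     collapse = ".."))),
          pth("panel_truth.tsv"), hdr)
        note(st, pipeline_artifacts$panel)
      },
      stats = {
        ann <- read_annotation(pth("annotation.tsv"))
        g <- read_panel(pth("panel.vcf"), ann, min_depth = cfg$min_depth)
        g <- apply_inbred_site_filters(g, min_lines = cfg$min_lines)
        gf <- apply_gene_filters(g, ann, min_sites = cfg$min_sites)
        message("  retained ", nrow(gf$genotypes$sites), " sites in ",
                sum(gf$genes$kept), " genes")
        panel <- read_line_panel(pth("lines.tsv"))
        div <- gene_diversity_table(gf$genotypes, ann)
        dxy <- dxy_table(gf$genotypes, panel)
        div$dxy <- dxy$dxy[match(div$gene_id, dxy$gene_id)]
        write_tsv_with_header(div, pth("gene_stats.tsv"), hdr)
        rs <- do.call(rbind, lapply(c("D", "D_MINUS"), function(cl) {
          lines <- panel$line_id[panel$class == cl]
          sub <- subset_genotypes(gf$genotypes,
                                  intersect(lines, gf$genotypes$line_ids))
          out <- region_summary(gene_diversity_table(sub, ann),
                                n_boot = cfg$n_boot,
                                seed = stage_seeds[[st]])
          out$class <- cl
          out
        }))
        write_tsv_with_header(rs, pth("region_summary.tsv"), hdr)
        ld <- gene_pair_ld(gf$genotypes)
        write_tsv_with_header(ld, pth("gene_pair_ld.tsv"), hdr)
        note(st, pipeline_artifacts$stats)
      },
      dating = {
        ann <- read_annotation(pth("annotation.tsv"))
        panel <- read_line_panel(pth("lines.tsv"))
        g <- read_panel(pth("panel.vcf"), ann, min_depth = cfg$min_depth)
        d_lines <- intersect(panel$line_id[panel$class == "D"], g$line_ids)
        mdl_sites <- g$sites$gene_id %in%
          ann$gene_id[ann$region == "MDL11"]
        gd <- subset_genotypes(g, d_lines, mdl_sites)
        dv <- count_derived_variants(gd, ann)
        th <- thomson_age(dv, mu = cfg$mu_grid)
        write_tsv_with_header(as.data.frame(th), pth("thomson.tsv"), hdr)
        note(st, pipeline_artifacts$dating)
      },
      flanks = {
        fsim <- do.call(simulate_swept_flank_haplotypes,
                        c(cfg$flanks, list(seed = stage_seeds[[st]])))
        hg <- assign_haplotype_groups(fsim$genotypes,
                                      focal_pos = fsim$truth$focal_pos)
        write_tsv_with_header(hg$summary, pth("haplotype_groups.tsv"), hdr)
        ages <- haplotype_age_from_length(
          c(mean = hg$mean_length_bp, median = hg$median_length_bp) / 1000,
          cfg$kb_per_cM_grid)
        write_tsv_with_header(as.data.frame(ages),
                              pth("haplotype_ages.tsv"), hdr)
        note(st, pipeline_artifacts$flanks)
      },
      scans = {
        ann <- read_annotation(pth("annotation.tsv"))
        stats_tab <- utils::read.delim(pth("gene_stats.tsv"),
                                       comment.char = "#")
        ord <- stats_tab[order(match(stats_tab$gene_id, ann$gene_id)), ]
        mdl <- which(ord$region == "MDL11")
        focal <- mdl[seq_len(min(cfg$block_size, length(mdl)))]
        bp <- block_permutation_test(ord$pi, focal,
                                     block_size = length(focal),
                                     n_perm = cfg$n_perm, side = "lower",
                                     seed = stage_seeds[[st]])
        write_tsv_with_header(
          data.frame(observed_mean = bp$observed_mean, p_value = bp$p_value,
                     side = bp$side, n_perm = bp$n_perm),
          pth("block_permutation.tsv"), hdr)
        d <- read_depth_matrix(pth("depth.tsv"), ann)
        panel <- read_line_panel(pth("lines.tsv"))
        cov <- classify_coverage_ratio(standardize_depth(d), panel)
        write_tsv_with_header(cov, pth("coverage_classes.tsv"), hdr)
        note(st, pipeline_artifacts$scans)
      },
      qtl = {
        ccfg <- do.call(cross_sim_config,
                        c(cfg$cross, list(seed = stage_seeds[[st]])))
        csim <- simulate_f2_cross(ccfg)
        pheno <- data.frame(
          f2_id = csim$f2$f2_id, mdl11 = csim$f2$mdl11,
          n_progeny = rowSums(csim$f2$f3_counts),
          pct_d_fem = estimate_drive_strength(csim$f2$f3_counts))
        write_tsv_with_header(pheno, pth("drive_phenotypes.tsv"), hdr)
        lp <- lod_scan(csim$f2)
        write_tsv_with_header(as.data.frame(lp), pth("lod_profile.tsv"), hdr)
        note(st, pipeline_artifacts$qtl)
      }
    )
  }
  manifest_path <- pth("manifest.tsv")
  if (file.exists(manifest_path)) {
    old <- utils::read.delim(manifest_path, comment.char = "#")
    manifest <- unique(rbind(old, manifest))
  }
  write_tsv_with_header(manifest, manifest_path,
                        stage_header("manifest", cfg$seed, cfg_hash))
  invisible(manifest)
}
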