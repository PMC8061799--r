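# Generators emulating the study's inputs with known truth: a swept inbred
# panel, swept-flank haplotype mosaics, and a three-parent F2 drive cross.
# Background polymorphism is site-i.i.d. with a neutral-like frequency
# spectrum (P(derived count = j) proportional to 1/j), a modelling
# convenience that makes Tajima's D ~ 0 under the null without running a
# coalescent simulation.

harmonic <- function(n) sum(1 / seq_len(n))

draw_sfs_counts <- function(n_sites, n_lines) {
  j <- seq_len(n_lines - 1)
  sample(j, n_sites, replace = TRUE, prob = 1 / j)
}

#' Configuration for the inbred-panel generator
#'
#' Defaults mirror the focal study panel: 34 inbred (effectively haploid)
#' lines of which 14 carry the driving haplotype, a 219-gene swept interval
#' (256,887 genotyped exonic positions, i.e. 1173 per gene) flanked by 855
#' polymorphic genes, background per-site diversity near 0.01, a 45-gene
#' interval deleted from the non-driving haplotype, and a sweep age of 300
#' generations at a mutation rate of 1e-8 (consistent with ~10 derived
#' mutations across the surveyed coding sequence).
#'
#' @param n_lines Panel size; default 34.
#' @param d_frequency Frequency of the driving class; default 14/34.
#' @param n_genes_mdl11,n_genes_flank Genes inside / outside the swept
#'   interval; defaults 219 and 855.
#' @param sites_per_gene Genotyped exonic positions per gene; default 1173.
#' @param gene_span Gene footprint in bp; default 3600.
#' @param sweep_age Generations since the driving haplotype's common
#'   ancestor; default 300.
#' @param mu Per-site per-generation mutation rate; default 1e-8.
#' @param pi_flanking,pi_dminus_mdl11 Per-site diversity targets; defaults
#'   0.0098 (all lines, flanking) and 0.0097 (non-driving lines, swept
#'   interval).
#' @param missing_rate Fraction of genotype cells set missing; default 0.05.
#' @param het_gene_fraction Fraction of genes emulating collapsed paralogs,
#'   where heterozygous calls concentrate; default 0.05.
#' @param het_site_rate Fraction of sites with heterozygous calls inside a
#'   collapsed-paralog gene; default 0.02 (more than 5 het sites per gene at
#'   the default gene size, so the het-gene filter removes them).
#' @param background_het_rate Per-site rate of isolated heterozygous calls
#'   elsewhere; default 2e-4.
#' @param n_deleted_genes Contiguous swept-interval genes deleted from the
#'   non-driving haplotype; default 45.
#' @param depth_sites_per_gene Exonic sites carried in the depth matrix per
#'   gene; default 20.
#' @param depth_mean Mean read depth; default 20.
#' @param depth_noise_sd Relative Gaussian depth noise (truncated at 0);
#'   default 0.1.
#' @param deleted_depth_sd Deleted-region standardized depth is
#'   `|N(0, deleted_depth_sd)|`; default 0.05.
#' @param chrom Chromosome label; default `"LG11"`.
#' @param seed Optional integer seed.
#' @return List of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_lines = 34, d_frequency = 14 / 34,
                             n_genes_mdl11 = 219, n_genes_flank = 855,
                             sites_per_gene = 1173, gene_span = 3600,
                             sweep_age = 300, mu = 1e-8,
                             pi_flanking = 0.0098, pi_dminus_mdl11 = 0.0097,
                             missing_rate = 0.05, het_gene_fraction = 0.05,
                             het_site_rate = 0.02, background_het_rate = 2e-4,
                             n_deleted_genes = 45, depth_sites_per_gene = 20,
                             depth_mean = 20, depth_noise_sd = 0.1,
                             deleted_depth_sd = 0.05, chrom = "LG11",
                             seed = NULL) {
  if (d_frequency <= 0 || d_frequency >= 1) stop("0 < d_frequency < 1")
  if (sweep_age < 0) stop("sweep_age must be >= 0")
  if (pi_flanking < 0 || pi_flanking > 0.5 ||
      pi_dminus_mdl11 < 0 || pi_dminus_mdl11 > 0.5) {
    stop("diversity targets must lie in [0, 0.5]")
  }
  n_d <- round(n_lines * d_frequency)
  if (n_d < 2 || n_lines - n_d < 2) stop("each class needs >= 2 lines")
  if (n_deleted_genes >= n_genes_mdl11) {
    stop("deleted interval must be smaller than the swept interval")
  }
  if (sites_per_gene > gene_span) stop("sites_per_gene exceeds gene_span")
  # feasibility of the site-i.i.d. diversity targets
  if (pi_flanking * harmonic(n_lines - 1) >= 1) {
    stop("infeasible flanking diversity target")
  }
  if (pi_dminus_mdl11 * harmonic(n_lines - n_d - 1) >= 1) {
    stop("infeasible swept-interval diversity target")
  }
  structure(as.list(environment()), class = "panel_sim_config")
}

#' Simulate an inbred resequencing panel with a planted sweep
#'
#' Driving-class lines are identical across the swept interval except for
#' private mutations drawn per line as `Poisson(mu * L * sweep_age)`
#' (star-phase mutation accumulation); non-driving lines in the swept
#' interval, and all lines in the flanking regions, carry site-i.i.d.
#' polymorphism calibrated so realized per-site diversity matches the
#' configured targets. Residual heterozygous calls, missing data, and a
#' zero-coverage deleted interval in non-driving lines are layered on top,
#' together with a read-depth matrix (mean 1 after standardization, Gaussian
#' noise, the deleted interval near 0).
#'
#' @param cfg A [panel_sim_config()].
#' @return List of class `panel_sim`: `genotypes` ([genotype_matrix()]),
#'   `annotation` (`gene_annotation`), `depth` ([depth_matrix()]), `panel`
#'   (`line_panel`) and `truth` (generator parameters plus realized latent
#'   values).
#' @export
simulate_inbred_panel <- function(cfg = panel_sim_config()) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_lines
  n_d <- round(n * cfg$d_frequency)
  n_dm <- n - n_d
  line_ids <- c(sprintf("D%03d", seq_len(n_d)),
                sprintf("DM%03d", seq_len(n_dm)))
  d_lines <- seq_len(n_d)
  dm_lines <- n_d + seq_len(n_dm)

  # gene layout: flanking-left | MDL11 (with deleted interval) | flanking-right
  n_left <- floor(cfg$n_genes_flank / 2)
  n_genes <- cfg$n_genes_flank + cfg$n_genes_mdl11
  region <- rep("FLANKING", n_genes)
  mdl11_idx <- n_left + seq_len(cfg$n_genes_mdl11)
  region[mdl11_idx] <- "MDL11"
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  start <- (seq_len(n_genes) - 1L) * cfg$gene_span + 1L
  end <- start + cfg$gene_span - 1L
  ann <- data.frame(gene_id = gene_id, chrom = cfg$chrom, start = start,
                    end = end, map_order = seq_len(n_genes), region = region,
                    stringsAsFactors = FALSE)
  ann$exon_list <- Map(function(s, e) cbind(start = s, end = e), start, end)
  ann <- as_gene_annotation(ann)

  spacing <- floor(cfg$gene_span / cfg$sites_per_gene)
  offs <- (seq_len(cfg$sites_per_gene) - 1L) * spacing
  pos <- as.integer(rep(start, each = cfg$sites_per_gene) + offs)
  site_gene <- rep(gene_id, each = cfg$sites_per_gene)
  site_region <- rep(region, each = cfg$sites_per_gene)
  S <- length(pos)
  calls <- matrix(0L, n, S, dimnames = list(line_ids, NULL))

  plant_poly <- function(site_idx, line_set, target_pi) {
    k <- length(line_set)
    w <- target_pi * harmonic(k - 1)
    poly <- site_idx[stats::runif(length(site_idx)) < w]
    if (!length(poly)) return(invisible(NULL))
    js <- draw_sfs_counts(length(poly), k)
    rows <- unlist(lapply(seq_along(poly), function(i) {
      line_set[sample.int(k, js[i])]
    }))
    cols <- rep(poly, js)
    calls[cbind(rows, cols)] <<- 1L
    invisible(NULL)
  }
  flank_sites <- which(site_region == "FLANKING")
  mdl_sites <- which(site_region == "MDL11")
  plant_poly(flank_sites, seq_len(n), cfg$pi_flanking)
  plant_poly(mdl_sites, dm_lines, cfg$pi_dminus_mdl11)

  # private mutations on the swept haplotype (star phase, per driving line)
  L_mdl <- length(mdl_sites)
  priv <- stats::rpois(n_d, cfg$mu * L_mdl * cfg$sweep_age)
  for (i in seq_len(n_d)) {
    if (priv[i] > 0) {
      calls[d_lines[i], sample(mdl_sites, priv[i])] <- 1L
    }
  }

  # residual heterozygous calls: concentrated in collapsed-paralog genes,
  # with a thin background of isolated het calls elsewhere
  het <- matrix(FALSE, n, S, dimnames = list(line_ids, NULL))
  n_het_genes <- round(cfg$het_gene_fraction * n_genes)
  het_genes <- if (n_het_genes > 0) sort(sample.int(n_genes, n_het_genes))
               else integer()
  hs <- integer()
  if (length(het_genes)) {
    in_het_gene <- which(rep(seq_len(n_genes), each = cfg$sites_per_gene)
                         %in% het_genes)
    hs <- in_het_gene[stats::runif(length(in_het_gene)) < cfg$het_site_rate]
  }
  bg <- setdiff(which(stats::runif(S) < cfg$background_het_rate), hs)
  for (s in c(hs, bg)) {
    carriers <- sample.int(n, 1L + stats::rbinom(1, 4, 0.25))
    het[carriers, s] <- TRUE
    calls[carriers, s] <- NA_integer_
  }

  # deleted interval: no reads from non-driving lines
  del_start <- floor(cfg$n_genes_mdl11 / 3)
  deleted_genes <- gene_id[mdl11_idx[del_start + seq_len(cfg$n_deleted_genes)]]
  del_sites <- which(site_gene %in% deleted_genes)
  calls[dm_lines, del_sites] <- NA_integer_
  het[dm_lines, del_sites] <- FALSE

  # uniform missingness
  if (cfg$missing_rate > 0) {
    nm <- round(cfg$missing_rate * length(calls))
    calls[sample.int(length(calls), nm)] <- NA_integer_
  }

  sites <- data.frame(chrom = cfg$chrom, pos = pos, ref = "A", alt = "T",
                      gene_id = site_gene, exonic = TRUE,
                      stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, sites, het_flags = het, line_ids = line_ids)

  # depth matrix on a per-gene subsample of exonic sites
  n_dsites <- min(cfg$depth_sites_per_gene, cfg$sites_per_gene)
  dsel <- as.vector(vapply(seq_len(n_genes), function(gi) {
    as.integer((gi - 1) * cfg$sites_per_gene) +
      sort(sample.int(cfg$sites_per_gene, n_dsites))
  }, integer(n_dsites)))
  nd <- length(dsel)
  depth <- matrix(pmax(0, cfg$depth_mean *
                         (1 + stats::rnorm(n * nd, sd = cfg$depth_noise_sd))),
                  n, nd, dimnames = list(line_ids, NULL))
  del_d <- which(site_gene[dsel] %in% deleted_genes)
  if (length(del_d)) {
    depth[dm_lines, del_d] <- cfg$depth_mean *
      abs(stats::rnorm(length(dm_lines) * length(del_d),
                       sd = cfg$deleted_depth_sd))
  }
  dm <- depth_matrix(depth,
                     data.frame(chrom = cfg$chrom, pos = pos[dsel],
                                gene_id = site_gene[dsel],
                                stringsAsFactors = FALSE),
                     line_ids = line_ids)

  panel <- as_line_panel(data.frame(
    line_id = line_ids,
    class = c(rep("D", n_d), rep("D_MINUS", n_dm)),
    population = "IM", stringsAsFactors = FALSE
  ))
  truth <- list(config = cfg, n_d = n_d, d_lines = line_ids[d_lines],
                dminus_lines = line_ids[dm_lines],
                deleted_genes = deleted_genes,
                private_mutations = stats::setNames(priv,
                                                    line_ids[d_lines]),
                L_mdl11_sites = L_mdl, mdl11_genes = gene_id[mdl11_idx],
                het_genes = gene_id[het_genes])
  structure(list(genotypes = g, annotation = ann, depth = dm, panel = panel,
                 truth = truth),
            class = "panel_sim")
}

#' Simulate swept-flank haplotype mosaics around a focal gene
#'
#' Emulates a phased display of intermediate-frequency SNPs around a swept
#' gene: lines fall into `n_groups` long-range haplotype groups, each group
#' sharing an unbroken segment around the focal position whose two sides are
#' independent exponentials with mean `1/(2 * true_age)` Morgans, so the
#' expected total shared length is `1/true_age` Morgans — the exact inverse
#' of the haplotype-length dating formula. Genetic length converts to
#' physical length via `kb_per_cM`. Outside its group segment each line
#' carries independent Bernoulli(1/2) background alleles; all lines share the
#' swept core allele at the marker nearest the focal position.
#'
#' @param n_lines Number of haploid lines; default 34.
#' @param true_age Sweep age in generations (> 0); default 300.
#' @param kb_per_cM Local recombination rate; default 500.
#' @param region_kb Displayed region length in kb; default 496.
#' @param marker_spacing_kb Marker spacing in kb; default 0.25.
#' @param n_groups Number of long-range haplotype backgrounds; default 7.
#' @param focal_pos Focal coordinate; defaults to the region centre.
#' @param region_start 1-based start coordinate; default 13,500,000.
#' @param chrom Chromosome label; default `"LG14"`.
#' @param seed Optional integer seed.
#' @return List of class `flank_sim`: `genotypes` ([genotype_matrix()]) and
#'   `truth` (group assignment, per-group true segment bounds and lengths).
#' @export
simulate_swept_flank_haplotypes <- function(n_lines = 34, true_age = 300,
                                            kb_per_cM = 500, region_kb = 496,
                                            marker_spacing_kb = 0.25,
                                            n_groups = 7, focal_pos = NULL,
                                            region_start = 13500000,
                                            chrom = "LG14", seed = NULL) {
  if (true_age <= 0) stop("true_age must be > 0")
  if (!is.null(seed)) set.seed(seed)
  pos <- as.integer(seq(region_start, region_start + region_kb * 1000,
                        by = marker_spacing_kb * 1000))
  S <- length(pos)
  if (is.null(focal_pos)) focal_pos <- pos[ceiling(S / 2)]
  expected_side_bp <- kb_per_cM * 1000 * 100 / (2 * true_age)
  if (expected_side_bp < 2 * marker_spacing_kb * 1000) {
    warning("marker grid too sparse to resolve expected haplotype lengths")
  }
  line_ids <- sprintf("L%03d", seq_len(n_lines))
  group_of <- sample.int(n_groups, n_lines, replace = TRUE)
  # per-group shared segments: each side Exp(mean 1/(2t) Morgans)
  bp_per_morgan <- kb_per_cM * 1000 * 100
  left_bp <- stats::rexp(n_groups, rate = 2 * true_age) * bp_per_morgan
  right_bp <- stats::rexp(n_groups, rate = 2 * true_age) * bp_per_morgan
  seg_start <- pmax(pos[1], round(focal_pos - left_bp))
  seg_end <- pmin(pos[S], round(focal_pos + right_bp))
  group_hap <- matrix(stats::rbinom(n_groups * S, 1, 0.5), n_groups, S)
  calls <- matrix(stats::rbinom(n_lines * S, 1, 0.5), n_lines, S,
                  dimnames = list(line_ids, NULL))
  for (i in seq_len(n_lines)) {
    gidx <- group_of[i]
    inside <- pos >= seg_start[gidx] & pos <= seg_end[gidx]
    calls[i, inside] <- group_hap[gidx, inside]
  }
  calls[, which.min(abs(pos - focal_pos))] <- 1L  # shared swept core allele
  storage.mode(calls) <- "integer"
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                      gene_id = NA_character_, exonic = TRUE,
                      stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, sites, line_ids = line_ids)
  truth <- list(true_age = true_age, kb_per_cM = kb_per_cM,
                focal_pos = focal_pos, group_of = stats::setNames(group_of,
                                                                  line_ids),
                seg_start = seg_start, seg_end = seg_end,
                seg_length_bp = seg_end - seg_start + 1,
                expected_total_bp = bp_per_morgan / true_age)
  structure(list(genotypes = g, truth = truth), class = "flank_sim")
}

#' Default marker map for the cross generator
#'
#' @param n_chrom Chromosomes; default 14.
#' @param markers_per_chrom Markers per chromosome; default 30.
#' @param spacing_cM Marker spacing in cM; default 3.
#' @return Data frame `marker`, `chrom`, `cM`.
#' @export
default_marker_map <- function(n_chrom = 14, markers_per_chrom = 30,
                               spacing_cM = 3) {
  data.frame(
    marker = sprintf("c%02dm%02d", rep(seq_len(n_chrom),
                                       each = markers_per_chrom),
                     rep(seq_len(markers_per_chrom), n_chrom)),
    chrom = rep(seq_len(n_chrom), each = markers_per_chrom),
    cM = rep((seq_len(markers_per_chrom) - 1) * spacing_cM, n_chrom),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the F2 drive-cross generator
#'
#' Defaults emulate the three-parent intercross: F2s segregate only the two
#' drive-locus heterozygote classes (the driving allele is transmitted by
#' the F1 mother), with realized female transmission 0.93 (heterospecific)
#' and 0.73 (conspecific) and 12-16 selfed progeny genotyped per family.
#'
#' @param n_f2 Number of F2 individuals; default 184.
#' @param marker_map Marker map data frame; default [default_marker_map()].
#' @param f_Dd,f_DDminus True female transmission per drive-locus class;
#'   defaults 0.93 and 0.73.
#' @param modifiers Optional data frame `marker`, `effect`: per-allele shift
#'   of the transmission rate, applied as `effect * (dosage - 1)` so the two
#'   homozygotes differ by `2 * effect`.
#' @param family_range Range of genotyped F3 progeny per family; default
#'   `c(12, 16)`.
#' @param miscall_rate Probability mass moved off the true genotype class in
#'   the emitted probability triples; default 0.02.
#' @param missing_rate Fraction of uninformative (1/3, 1/3, 1/3) marker
#'   probability triples; default 0.05.
#' @param seed Optional integer seed.
#' @return List of class `cross_sim_config`.
#' @export
cross_sim_config <- function(n_f2 = 184, marker_map = default_marker_map(),
                             f_Dd = 0.93, f_DDminus = 0.73, modifiers = NULL,
                             family_range = c(12, 16), miscall_rate = 0.02,
                             missing_rate = 0.05, seed = NULL) {
  if (f_Dd < 0 || f_Dd > 1 || f_DDminus < 0 || f_DDminus > 1) {
    stop("transmission rates must lie in [0, 1]")
  }
  if (!is.null(modifiers)) {
    stopifnot(all(c("marker", "effect") %in% names(modifiers)),
              all(modifiers$marker %in% marker_map$marker))
  }
  stopifnot(length(family_range) == 2, family_range[1] >= 1,
            family_range[1] <= family_range[2])
  structure(as.list(environment()), class = "cross_sim_config")
}

#' Simulate a three-parent F2 drive cross with selfed F3 progeny
#'
#' Drive-locus genotypes are Bernoulli(1/2) between the two heterozygote
#' classes (the F1 mother transmits only the driving allele). Marker
#' genotypes arise from two independent gametes per F2, each a Markov chain
#' along the chromosome with Haldane map-function recombination between
#' adjacent markers. Each F2's true female transmission is its class base
#' rate plus any planted modifier effects (clipped to `[0, 1]`); F3 genotype
#' counts are multinomial draws assuming Mendelian transmission through
#' pollen. Genotype-probability triples are emitted with configurable
#' calling noise.
#'
#' @param cfg A [cross_sim_config()].
#' @return List of class `cross_sim`: `f2` ([f2_records()]) and `truth`
#'   (true dosages, true transmission rates, modifier placement).
#' @export
simulate_f2_cross <- function(cfg = cross_sim_config()) {
  stopifnot(inherits(cfg, "cross_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  map <- cfg$marker_map
  n <- cfg$n_f2
  m <- nrow(map)
  mdl11 <- sample(c("Dd", "DD_MINUS"), n, replace = TRUE)
  sim_gamete <- function() {
    g <- matrix(0L, n, m)
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      g[, idx[1]] <- stats::rbinom(n, 1, 0.5)
      if (length(idx) > 1) {
        d <- diff(map$cM[idx])
        r <- 0.5 * (1 - exp(-2 * d / 100))
        for (k in seq_along(d)) {
          sw <- stats::rbinom(n, 1, r[k])
          g[, idx[k + 1]] <- ifelse(sw == 1L, 1L - g[, idx[k]], g[, idx[k]])
        }
      }
    }
    g
  }
  dosage <- sim_gamete() + sim_gamete()  # count of driving-species alleles
  f_true <- ifelse(mdl11 == "Dd", cfg$f_Dd, cfg$f_DDminus)
  if (!is.null(cfg$modifiers)) {
    for (k in seq_len(nrow(cfg$modifiers))) {
      j <- match(cfg$modifiers$marker[k], map$marker)
      f_true <- f_true + cfg$modifiers$effect[k] * (dosage[, j] - 1)
    }
  }
  f_true <- pmin(pmax(f_true, 0), 1)
  sizes <- seq(cfg$family_range[1], cfg$family_range[2])
  n_prog <- sizes[sample.int(length(sizes), n, replace = TRUE)]
  f3 <- t(vapply(seq_len(n), function(i) {
    as.integer(stats::rmultinom(1, n_prog[i],
                                c(f_true[i] / 2, 0.5, (1 - f_true[i]) / 2)))
  }, integer(3)))
  colnames(f3) <- c("n_DD", "n_Dhet", "n_other")
  # genotype-probability triples with calling noise
  probs <- array(cfg$miscall_rate / 2, dim = c(n, m, 3),
                 dimnames = list(NULL, map$marker, c("GG", "NG", "NN")))
  true_class <- 3L - dosage  # dosage 2 -> GG(1), 1 -> NG(2), 0 -> NN(3)
  for (cl in 1:3) {
    sel <- true_class == cl
    idx <- which(sel, arr.ind = TRUE)
    probs[cbind(idx, cl)] <- 1 - cfg$miscall_rate
  }
  if (cfg$missing_rate > 0) {
    nmiss <- round(cfg$missing_rate * n * m)
    cells <- arrayInd(sample.int(n * m, nmiss), c(n, m))
    for (cl in 1:3) probs[cbind(cells, cl)] <- 1 / 3
  }
  f2 <- f2_records(sprintf("F2_%03d", seq_len(n)), mdl11, probs, map, f3)
  truth <- list(config = cfg, dosage = dosage, f_true = f_true,
                mdl11 = mdl11, n_prog = n_prog)
  structure(list(f2 = f2, truth = truth), class = "cross_sim")
}
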