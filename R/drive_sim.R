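#' Configuration for the drive-haplotype simulator
#'
#' Defaults reproduce the study conditions of the forward experiment: a
#' founder population of 20 non-recombining chromosomes growing by 10% per
#' generation to a cap of 50,000, a locus of 256,867 high-confidence coding
#' positions, 13 chromosomes sampled per generation and a stopping rule of 9
#' observed segregating sites.
#'
#' @param founder_n Founder chromosomes; default 20.
#' @param growth Per-generation growth factor; default 1.10.
#' @param n_max Chromosome cap; default 50000.
#' @param L Locus positions; default 256867.
#' @param mu Per-site per-generation mutation rate; default 1e-8.
#' @param sample_n Chromosomes sampled per generation; default 13.
#' @param stop_S Segregating-site stopping threshold; default 9.
#' @param max_gen Censoring guard; default 50000.
#' @param seed Optional integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(founder_n = 20, growth = 1.10, n_max = 50000,
                       L = 256867, mu = 1e-8, sample_n = 13, stop_S = 9,
                       max_gen = 50000, seed = NULL) {
  if (founder_n < 2) stop("founder_n must be >= 2")
  if (growth <= 1) stop("growth must be > 1")
  if (n_max < founder_n) stop("n_max must be >= founder_n")
  if (mu < 0) stop("mu must be >= 0")
  if (sample_n > founder_n) stop("sample_n must be <= founder_n")
  structure(list(founder_n = as.integer(founder_n), growth = growth,
                 n_max = as.integer(n_max), L = L, mu = mu,
                 sample_n = as.integer(sample_n), stop_S = as.integer(stop_S),
                 max_gen = as.integer(max_gen), seed = seed),
            class = "sim_config")
}

#' Simulate neutral mutation accumulation on an expanding drive haplotype
#'
#' Haploid Wright-Fisher reproduction (uniform parent choice with
#' replacement) on a non-recombining chromosome; each offspring gains
#' `Poisson(mu * L)` new mutations at uniform positions (finite sites, repeat
#' hits flip the allele back). The population grows from the founder
#' bottleneck with chromosome counts kept even,
#' `N_{t+1} = min(2 * floor(growth * N_t / 2), n_max)`, the founder
#' generation counted as generation 1. Each generation, `sample_n`
#' chromosomes are drawn without replacement (post-reproduction census) and
#' scored for segregating sites; the run records the first generation whose
#' sampled count reaches `stop_S`.
#'
#' @param cfg A [sim_config()].
#' @param track_history Keep per-generation population mutation sets (tiny
#'   runs only); default FALSE.
#' @return Object of class `drive_sim_result`: `stop_generation` (integer, or
#'   `NA` if censored at `max_gen`), `censored`, `s_trajectory`,
#'   `x_trajectory` (per-generation total derived-allele count over
#'   segregating sites in the sample, the Thomson numerator), `pop_sizes`,
#'   `config` and (optionally) `history`.
#' @export
simulate_drive_haplotype <- function(cfg = sim_config(),
                                     track_history = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- wf_sim_cpp(cfg$founder_n, cfg$growth, cfg$n_max, cfg$mu, cfg$L,
                    cfg$sample_n, cfg$stop_S, cfg$max_gen, track_history)
  structure(list(stop_generation = res$stop_generation,
                 censored = is.na(res$stop_generation),
                 s_trajectory = res$s_trajectory,
                 x_trajectory = res$x_trajectory,
                 pop_sizes = res$pop_sizes,
                 history = res$history,
                 config = cfg),
            class = "drive_sim_result")
}

#' @export
print.drive_sim_result <- function(x, ...) {
  if (x$censored) {
    cat("<drive_sim_result> censored at generation",
        length(x$s_trajectory), "\n")
  } else {
    cat("<drive_sim_result> stopped at generation", x$stop_generation,
        "with S =", utils::tail(x$s_trajectory, 1), "\n")
  }
  invisible(x)
}

#' Star-genealogy expectation for the stopping generation
#'
#' Under a star genealogy the sampled lineages accumulate mutations
#' independently at rate `mu * L` each, so `stop_S` segregating sites are
#' expected after `stop_S / (sample_n * mu * L)` generations. Serves as the
#' analytic oracle for [simulate_drive_haplotype()].
#'
#' @param stop_S Segregating-site threshold.
#' @param sample_n Sampled chromosomes.
#' @param mu Per-site per-generation mutation rate.
#' @param L Locus positions.
#' @return Expected stopping generation (numeric).
#' @export
star_expected_stop <- function(stop_S, sample_n, mu, L) {
  if (any(c(stop_S, sample_n, mu, L) <= 0)) {
    stop("all arguments must be positive")
  }
  stop_S / (sample_n * mu * L)
}

#' Run the simulator over a mutation-rate / population-size grid
#'
#' Per-replicate seeds are derived deterministically from the master seed, so
#' the grid is reproducible and individual cells can be re-run in isolation.
#'
#' @param mu_values Mutation-rate grid.
#' @param n_max_values Population-cap grid.
#' @param reps Replicates per cell (0 gives an empty table).
#' @param seed Master seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return Data frame: `mu`, `n_max`, `rep`, `seed`, `stop_generation`,
#'   `censored`.
#' @export
run_simulation_grid <- function(mu_values, n_max_values, reps, seed, ...) {
  stopifnot(length(mu_values) >= 1, length(n_max_values) >= 1)
  cells <- expand.grid(mu = mu_values, n_max = n_max_values,
                       rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE)
  if (!nrow(cells)) {
    return(data.frame(mu = numeric(), n_max = numeric(), rep = integer(),
                      seed = integer(), stop_generation = integer(),
                      censored = logical()))
  }
  set.seed(seed)
  cells$seed <- sample.int(.Machine$integer.max, nrow(cells))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- sim_config(mu = cells$mu[i], n_max = cells$n_max[i],
                      seed = cells$seed[i], ...)
    r <- simulate_drive_haplotype(cfg)
    data.frame(mu = cells$mu[i], n_max = cells$n_max[i], rep = cells$rep[i],
               seed = cells$seed[i],
               stop_generation = ifelse(r$censored, NA_integer_,
                                        r$stop_generation),
               censored = r$censored)
  })
  do.call(rbind, out)
}

#' Generations of growth to reach a target population size
#'
#' Under the simulator's growth convention (even chromosome counts,
#' `N_{t+1} = 2 * floor(growth * N_t / 2)`, founder generation = 1), the
#' first generation at which the chromosome count reaches `target`. With the
#' defaults this gives 89 generations to 50,000 chromosomes and 113 to
#' 500,000.
#'
#' @param target Target chromosome count.
#' @param founder_n Founder chromosomes; default 20.
#' @param growth Growth factor; default 1.10.
#' @return Integer generation index.
#' @export
generations_of_growth <- function(target, founder_n = 20, growth = 1.10) {
  N <- founder_n
  t <- 1L
  while (N < target) {
    N2 <- 2 * floor(growth * N / 2)
    if (N2 <= N) stop("population cannot reach target under this growth rate")
    N <- N2
    t <- t + 1L
  }
  t
}
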