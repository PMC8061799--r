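#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// Forward Wright-Fisher simulation of neutral mutation accumulation on a
// non-recombining haploid chromosome population expanding from a founder
// bottleneck. Finite sites with repeat hits allowed: a second hit at a
// segregating position flips the carrier back (symmetric mutation).
//
// Growth convention: chromosome counts are kept even (chromosomes come in
// diploid individuals); N_{t+1} = min(2*floor(growth*N_t/2), n_max). The
// founder population is generation 1. Each generation the current population
// is sampled (sample_n chromosomes without replacement, or all if fewer) and
// the number of segregating sites in the sample is recorded; the run stops
// at the first generation whose sampled S reaches stop_S.
//
// Uses R's RNG throughout, so results are reproducible under set.seed().

// Segregating sites (S) and total derived-allele count over segregating
// sites (sum_x) in a without-replacement sample of the current population.
static void sample_S(const std::vector<std::vector<int> > &pop,
                     int sample_n, int *S_out, int *sumx_out) {
  int N = pop.size();
  int k = std::min(sample_n, N);
  // partial Fisher-Yates over indices
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::unordered_map<int, int> carriers;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (N - i));
    if (j >= N) j = N - 1;
    std::swap(idx[i], idx[j]);
    const std::vector<int> &mut = pop[idx[i]];
    for (size_t m = 0; m < mut.size(); ++m) carriers[mut[m]]++;
  }
  int S = 0, sumx = 0;
  for (std::unordered_map<int, int>::const_iterator it = carriers.begin();
       it != carriers.end(); ++it) {
    if (it->second > 0 && it->second < k) {
      ++S;
      sumx += it->second;
    }
  }
  *S_out = S;
  *sumx_out = sumx;
}

// [[Rcpp::export]]
List wf_sim_cpp(int founder_n, double growth, int n_max, double mu, double L,
                int sample_n, int stop_S, int max_gen, bool track_history) {
  std::vector<std::vector<int> > pop(founder_n);
  std::vector<int> s_traj;
  std::vector<int> x_traj;
  std::vector<double> pop_sizes;
  List history;
  int stop_generation = NA_INTEGER;
  double lambda = mu * L;

  for (int gen = 1; gen <= max_gen; ++gen) {
    int N = pop.size();
    pop_sizes.push_back((double)N);
    int S, sumx;
    sample_S(pop, sample_n, &S, &sumx);
    s_traj.push_back(S);
    x_traj.push_back(sumx);
    if (track_history) {
      List snapshot(N);
      for (int i = 0; i < N; ++i) snapshot[i] = wrap(pop[i]);
      history.push_back(snapshot);
    }
    if (S >= stop_S) {
      stop_generation = gen;
      break;
    }
    if (gen == max_gen) break;
    // next population size (even chromosome counts, capped)
    long next_half = (long)std::floor(growth * (N / 2.0));
    long N_next = std::min((long)n_max, 2L * next_half);
    if (N_next < 2) N_next = 2;
    std::vector<std::vector<int> > next_pop((size_t)N_next);
    for (long j = 0; j < N_next; ++j) {
      int parent = (int)(unif_rand() * N);
      if (parent >= N) parent = N - 1;
      next_pop[j] = pop[parent];
      if (lambda > 0) {
        int nmut = (int)R::rpois(lambda);
        for (int m = 0; m < nmut; ++m) {
          int posn = (int)(unif_rand() * L);
          std::vector<int> &v = next_pop[j];
          std::vector<int>::iterator hit = std::find(v.begin(), v.end(), posn);
          if (hit != v.end()) v.erase(hit);  // back-mutation by flip
          else v.push_back(posn);
        }
      }
    }
    pop.swap(next_pop);
    if ((gen & 63) == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["stop_generation"] = stop_generation,
    _["s_trajectory"] = wrap(s_traj),
    _["x_trajectory"] = wrap(x_traj),
    _["pop_sizes"] = wrap(pop_sizes)
  );
  if (track_history) out["history"] = history;
  return out;
}
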