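---
title: "Models and methods for dating centromere-associated sweeps and mapping drive modifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for dating centromere-associated sweeps and mapping drive modifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrodrive)
```

This vignette documents the statistical models behind `centrodrive`, the
choices made where the methods literature leaves latitude, and what the
synthetic-data generators do and do not emulate. The system in mind is a
plant population polymorphic for a driving centromeric haplotype: the driver
(*D*) is a multi-megabase, recombination-suppressed block held at
intermediate frequency by a balance between female meiotic drive and
homozygous fitness costs, and its spread is expected to leave (i) a hard
partial sweep across the block itself and (ii) a response sweep at unlinked
kinetochore genes such as CenH3.

## Panel representation and filters

Inbred lines are represented **haploid**: a homozygous diploid VCF call
collapses to one allele code. An originally heterozygous call cannot be
collapsed; it is stored as missing with a separate heterozygosity flag,
because residual heterozygosity in highly inbred lines almost always marks
collapsed paralogs or alignment artefacts rather than real variation. The
filter chain is fixed and ordered:

1. per-genotype depth `< 3` reads → missing (`read_panel`);
2. any flagged heterozygous call → the whole site is removed
   (`apply_inbred_site_filters`), *before*
3. sites with fewer than 10 called lines are removed, so a heterozygous
   call never counts toward the call threshold;
4. genes with fewer than 150 retained sites are dropped
   (`apply_gene_filters`).

Missingness is a first-class code: every statistic recomputes the per-site
sample size $n_s$ over non-missing calls. The copy-number path deliberately
bypasses the depth and heterozygosity filters (`read_depth_matrix`), since
deletions manifest precisely as sites those filters would discard.

## Diversity statistics

Per-gene nucleotide diversity is Nei's unbiased per-site heterozygosity,
$\pi = \sum_s \frac{a_s b_s}{\binom{n_s}{2}} / n_\mathrm{sites}$, with
allele counts $a_s, b_s$ over the $n_s$ lines called at site $s$. Sites
with $n_s < 2$ carry no pairwise information; they are excluded from both
the numerator and the retained-site denominator and reported in a flag
count, rather than being averaged in as zeros. Tajima's D uses the standard
constants ($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$) evaluated at the
per-gene mean $n_s$ rounded to the nearest integer — an approximation that
is exact for complete data and mild for the missingness rates the filters
allow; the value is undefined when no site segregates. $d_{xy}$ averages
the cross-class mismatch fraction per site; a site where either class is
entirely missing is excluded, and a gene with no usable site is undefined,
never zero. Linkage disequilibrium is the squared Pearson correlation of
0/1 haploid codes (equal to $D^2/(p_1 q_1 p_2 q_2)$), computed per SNP pair
over jointly called lines (at least 4), skipping pairs monomorphic among
those lines, and averaged over all cross-gene SNP pairs per gene pair.

Confidence intervals are percentile bootstrap over genes (N = 1000 by
default), resampling $n$ of $n$ **with** replacement: resampling without
replacement at full sample size would return the sample mean identically,
so the conventional percentile bootstrap is the only operable reading. The
reported standard error is the bootstrap standard deviation of the mean.

## Two sweep clocks

**Mutation accumulation (Thomson estimator).** A non-recombining haplotype
descending from a single recent ancestor accumulates derived mutations
independently along each sampled lineage, so
$\hat t = \sum_i x_i / (n \mu L)$, with $x_i$ the derived count of variant
$i$ among $n$ lines and $L$ the surveyed positions. The analysis is
restricted to exonic positions; sites flagged heterozygous are removed and
whole genes with more than 5 heterozygous exonic sites are excluded, since
clustered hets mark stacked copy-number variants whose apparent SNVs are
artefacts. The ancestral allele is the majority allele among the focal
lines, with exact ties resolved toward the reference allele (the reference
line belongs to the driving class, so its allele is the best tie-break
available). With missing data the denominator uses the *effective* length
$L_\mathrm{eff} = (\text{called cells})/n$, i.e. the mean number of
positions actually surveyed per line — otherwise a 5% missingness rate
would deflate every age by 5%. The estimator ignores the initial spread of
the haplotype to its equilibrium frequency and therefore underestimates the
true TMRCA; for a strong driver that phase is short.

**Haplotype-length decay.** A haplotype left unbroken over genetic length
$g$ Morgans around a selected site implies on the order of one
recombination since selection began, giving $t = 1/g$ generations, i.e.
$t = 100 \cdot (\text{kb/cM}) / \text{length}_\mathrm{kb}$. Because local
recombination rates are uncertain, ages are reported over the full
Cartesian product of the length summaries and the 150–1000 kb/cM rate
range; no averaging across grid points is performed, since any single
summary would hide that the rate is the dominant unknown. Generations are
equated with years throughout (annual plant).

Haplotype groups are assigned algorithmically (`assign_haplotype_groups`)
in place of manual curation: a greedy pass seeds a group with the first
unassigned line and admits a candidate when it matches the seed at the 5
nearest jointly genotyped SNPs on each side of the focal position (zero
mismatches tolerated by default). This nearest-flanking-marker rule is the
operational form of "shares an extended haplotype around the focal gene":
with intermediate-frequency display SNPs, ten chance matches have
probability $2^{-10}$, so false joins are rare, while true group members by
construction match across their entire shared segment. Each group's
segment is then measured with `shared_core_segment`, which expands from the
focal position to the first informative mismatch on each side and places
the boundary at the **midpoint** between the outermost matching and first
mismatching SNP — the least-biased convention when the true breakpoint
between observed markers is unobserved. If no mismatch occurs before the
genotyped region ends, the boundary is the outermost genotyped position
(lengths are then right-censored by the display window, as in any finite
region).

## The forward drive-haplotype simulator

`simulate_drive_haplotype` is a haploid Wright–Fisher model of a
non-recombining chromosome population: uniform parent choice with
replacement, $\mathrm{Poisson}(\mu L)$ new mutations per offspring at
uniform positions (finite sites; a repeat hit flips the allele back, a
negligible correction at $\mu L \approx 2.6\times10^{-3}$), growth by 10%
per generation from 20 founder chromosomes to a cap, and a
without-replacement sample of 13 chromosomes scored each generation for
segregating sites, stopping at the first sample showing 9 or more. The
inner loop is compiled (Rcpp) and uses R's RNG, so runs are bit-identical
under a fixed seed.

**Growth convention.** Chromosome counts are kept even — chromosomes come
in diploid individuals — and the per-generation update is
$N_{t+1} = \min(2\lfloor 1.1\, N_t/2 \rfloor,\ N_\mathrm{max})$ with the
founder generation counted as generation 1. This convention is pinned by
the expansion times it must reproduce: 89 generations from 20 to 50,000
chromosomes and 113 to 500,000 (`generations_of_growth`). A closed-form
update $\lceil 20 \cdot 1.1^t \rceil$ reaches 50,000 in 83 generations and
is therefore not the schedule those times describe; the floor-type update
at the diploid scale reproduces both.

**What the stopping rule measures.** The star-genealogy oracle
`star_expected_stop` gives the generation at which the *expected* sampled
segregating-site count reaches the threshold,
$S^*/(13\,\mu L) \approx 270$ at $\mu = 10^{-8}$. The simulator's recorded
stopping generation sits systematically below this for two reasons that
are properties of the experiment, not of the implementation: lineages
share ancestry during the founder/growth phase (mutations on shared
branches are counted once, and sample-fixed sites not at all), deflating
the expected sampled count by roughly a fifth at generation 270; and
stopping at the *first* generation whose freshly drawn sample crosses the
threshold is a first-passage time of a fluctuating count, which occurs
well before the mean crosses. The engine itself is validated two
independent ways: against a plain-R brute-force reimplementation at small
scale, and against Watterson's equilibrium
$E[S_k] = 2N\mu L\, a_{k-1}$ in constant-size runs. Thomson dating applied
to the sample at a *fixed* generation (via the recorded `x_trajectory`)
recovers that generation closely, confirming that the discrepancy lives in
the stopping rule, not the mutation accounting.

## Genome scans

The block-permutation test compares a focal run of 8 consecutive genes
against means of 500 randomly placed contiguous 8-gene windows on the same
chromosome. Null windows may overlap the focal block by default (nothing
in the procedure's definition excludes them; exclusion is available as a
flag and matters little on a chromosome hundreds of genes long). The
p-value uses the add-one convention $p = (1 + \#\{\text{null} \le
\text{obs}\})/(N+1)$, so it is never zero and is well calibrated under an
i.i.d. null. Permutation p-values are invariant to affine transformation
of the statistic.

Copy-number classification standardizes each depth cell by the line's
chromosome-wide median exonic depth, averages per gene, excludes genes
whose driving-class mean falls outside $[0.5, 3]$ (likely misassembly or
repeats), and bins the non-driving/driving coverage ratio: $\le 0.25$
deleted, $\ge 1.75$ duplicated, otherwise normal. Ratios above 2.0 are
still classed duplicated — display tracks cap at 2 only for plotting.

## Drive phenotype and the modifier scan

For a selfed heterozygous F2 mother, the driven-allele frequency among
progeny alleles is $p = (f + m)/2$ with $f$ the female and $m = 0.5$ the
assumed Mendelian male transmission. The method-of-moments inversion of
the allele-frequency estimate $\hat p = (2 n_{DD} + n_{Dhet}) / (2 n)$
gives $\hat f = 2\hat p - 0.5$, clipped to $[0,1]$. The clip introduces a
small bias only when $f$ is near the boundary and families are small; at
family size 1000 the bias is below 0.01.

The scan regresses $\hat f$ on the expected driven-species allele dosage
$2P(GG) + P(NG)$ computed from the genotype-probability triples
(Haley–Knott regression at observed markers; at typical marker densities
this coincides closely with EM interval mapping and is fully
specifiable). The drive-locus genotype enters both nested models as a
binary cofactor, so $\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$ measures
the marker's effect *beyond* the drive locus. Individuals are filtered
first: at least 12 genotyped progeny behind the phenotype and at most 50%
missing hardened calls (a call requires one genotype's probability
strictly above 0.8). The significance threshold is fixed at LOD = 2.0; no
permutation thresholding is applied by default. The smoothed trace is a
centred moving average of 4 markers, truncated at the trace edges
(position $i$ averages markers $i-1$ through $i+2$). The ANOVA of
transmission on modifier genotype (4 levels), drive-locus class (2
levels) and their interaction uses Type-II sums of squares, appropriate
for the unbalanced counts of a real intercross; noise-free inputs fall
back to an explicit nested-RSS decomposition.

## What the generators emulate — and what they do not

`simulate_inbred_panel` plants the full observable structure of the study
panel: 34 haploid lines (14 driving), a 219-gene swept interval that is
invariant in the driving class except per-line
$\mathrm{Poisson}(\mu L t)$ private mutations (star-phase accumulation),
background polymorphism calibrated so realized $\pi$ matches the targets
(0.0097–0.0098), missingness at 5%, heterozygous calls concentrated in a
5% fraction of collapsed-paralog genes (plus a $2\times10^{-4}$ per-site
background), a 45-gene interval with near-zero coverage in non-driving
lines, and a depth matrix with 10% relative Gaussian noise. Background
polymorphism is site-i.i.d. with derived-allele counts drawn
$P(j) \propto 1/j$ — the neutral frequency spectrum — so Tajima's D is
approximately zero under the null. This is a modelling convenience, not a
coalescent simulation: there is no linkage disequilibrium within the
background, no demography, and no recombination graph, so tests passing on
these panels certify the estimators' arithmetic and filter logic, not
robustness to correlated genealogies.

`simulate_swept_flank_haplotypes` is built to be the exact inverse of the
length clock: 7 haplotype groups, each sharing a segment whose two sides
are independent exponentials with mean $1/(2t)$ Morgans, so the expected
total shared length is $1/t$ Morgans (the factor of two is per side);
display markers are intermediate-frequency (Bernoulli(1/2) backgrounds),
as in a phased display of common SNPs. `simulate_f2_cross` draws the
drive-locus class Bernoulli(1/2) (the F1 mother transmits only the
driver), marker genotypes from two Haldane-map Markov-chain gametes,
per-family sizes uniform on 12–16, and multinomial selfed-progeny counts;
its default transmission rates (0.93 heterospecific, 0.73 conspecific) are
the realized cohort means of the mapping experiment, while the
expectations 0.98/0.58 from prior crosses are available as explicit
arguments.

## Problem sizes and numerical choices

The test suite runs the estimators at the study's swept-interval geometry
(219 genes × 1173 exonic positions = 256,887 sites) with reduced flanking
regions where flanking scale does not enter the quantity under test;
recovery checks use 10–20 replicates for Monte-Carlo means, 100 replicates
for the modifier-scan power estimate, and 200 replicates for the
simulator's stopping-generation distribution. Haplotype-length recovery
pools group lengths across replicates before inverting, because
$E[1/\bar X] > 1/E[\bar X]$ inflates a per-replicate inversion by
$\sim 8\%$ at 7 groups. Degenerate inputs are handled explicitly
throughout: empty filter output raises an error rather than returning an
empty success; a phenotype fully explained by the cofactor scores LOD 0
everywhere; a zero-variance marker is flagged rather than fitted; all-tied
bootstrap input returns a degenerate interval.

## Known limitations

- The background-polymorphism model carries no within-region LD, so LD
  heatmap structure in synthetic panels comes entirely from the planted
  sweep.
- Tajima's D with heavy, uneven missingness uses a single rounded mean
  sample size per gene; genes with pathological missingness patterns are
  better judged by their flag counts.
- The haplotype-group rule assumes dense, intermediate-frequency display
  markers; with sparse or skewed markers the 5-SNP matching window should
  be widened.
- The simulator's stopping-generation distribution is a first-passage
  time and should not be compared directly to an expected-count crossing
  (see above); use the fixed-generation `x_trajectory` for estimator
  validation.
- No coalescent-likelihood or ARG-based dating is attempted; the two
  clocks are deliberately simple and their disagreement under a soft sweep
  is informative rather than an error.
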