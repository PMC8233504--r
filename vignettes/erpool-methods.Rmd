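---
title: "Models and methods behind erpool"
author: "erpool authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpool)
```

# The experimental design the package models

erpool analyses evolve-and-resequence (E&R) experiments in which replicate
populations evolve under two selective regimes — here six "Selected"
populations adapted to a nutrient-poor larval diet and six "Control"
populations kept on a standard diet — for on the order of 150 generations,
after which each population is sequenced as a pool of 400 females at a
read depth of roughly 30–46x. The data enter the pipeline as a sync-format
count table: per site and population, read counts for A, T, C, G, N and
deletions. Every inference in the package is built on two facts about
such data:

1. Replicate populations drift independently, so the among-replicate
   variance of allele frequencies carries information about the effective
   population size and about selection (parallel shifts between regimes).
2. Pool-seq adds two binomial sampling layers on top of the true
   population frequency: `2S` chromosomes are drawn into the pool, and
   `R` reads are drawn from the pool.

# The synthetic-data generator

`simulate_experiment()` evolves each locus forward in time as a
Wright–Fisher population of diploid size `Ne` per regime: one shared
founder frequency per locus (or per linkage block), then `t` generations
of optional viability selection followed by binomial resampling of `2Ne`
chromosomes. Selection acts in the Selected regime only:

* **directional** — additive fitnesses `1, 1+s/2, 1+s` for the three
  genotypes of the favoured allele;
* **balanced** — overdominance parameterised directly by the requested
  equilibrium frequency `e`: homozygote fitnesses `1 - s(1-e)` and
  `1 - s e` around a heterozygote of fitness 1, which has its interior
  equilibrium exactly at `e`. Overdominance is the simplest mechanism
  with a controllable equilibrium; the package makes no claim about the
  mechanism of balancing selection in real data.

**Linkage blocks** are simulated as shared latent trajectories: all loci
of a block follow one Wright–Fisher path and each member adds independent
Gaussian jitter (SD 0.02 by default) to its final frequency. This is not
a recombining haplotype model; it is the minimal structure that produces
within-block residual correlations above 0.8 and between-block
correlations near zero, which is exactly what the downstream clustering
consumes. Recombination maps, inversions, demography and sex chromosomes
are out of scope; chromosome labels are purely positional.

**Pool sampling** (`sample_poolseq()`) is the exact two-stage binomial:
pool frequency `g ~ Binom(2S, p)/2S`, then `alt ~ Binom(R, g)` with
`R` drawn per site and population from a truncated-at-1 Poisson with mean
40 (within the study's 30–46x range; a negative binomial is available via
`depth_dispersion`). The exact read-frequency variance of this process is
`p(1-p)[1/(2S) + 1/R - 1/(2SR)]`, whereas the estimator below uses the
conventional correction `C = 1/(2S) + 1/R + 1/(SR)`; at `S = 400`,
`R = 30` the two differ by under 0.4% of `C`, far below the drift
variance the estimator targets.

**Founder frequencies** default to Beta(0.2, 0.2) truncated (by inverse
CDF, so no boundary atoms) to [0.02, 0.98] — the U-shaped spectrum
typical of laboratory populations derived from wild collections. The
source study does not report the base population's spectrum; this default
is a stand-in, not an inference, and is fully configurable.

# SNP calling and coverage homogenisation

`call_snps()` applies the heuristic pool-seq site filters in sequence:
user-supplied BED masks (indel neighbourhoods, transposable elements —
the package never inspects alignments itself); per-population coverage
bounds (at least 10 reads and at most the 95th coverage percentile of
that chromosome and population, estimated from the input table itself);
removal of sites where more than 20% of populations violate the bounds;
allele resolution on counts pooled across in-bounds populations, keeping
biallelic sites whose pooled minor allele has count ≥ 20 and frequency
≥ 1%. A site whose second and third allele counts tie is dropped as
ambiguous — a conservative, deterministic tie-break. Because the
maximum-coverage threshold is re-estimated from whatever table it is
given, re-filtering an already filtered table with a percentile below 100
can remove further sites; the other rules are idempotent.

Two subsampling modes homogenise coverage (`subsample_coverage()`):
*scan* mode hypergeometrically downsamples to exactly the target (30x by
default) and drops sites below target in any population — used by the
Fisher-exact scan so that every population contributes equal read
numbers; *popgen* mode additionally resamples shallow sites with
replacement up to the target, 30 times, and the diversity statistics are
computed per repetition and averaged — low-coverage sites are thereby
retained at the cost of some pseudo-replication, which the averaging
keeps unbiased for the mean.

# Diversity statistics

With coverage homogenised to `m` reads, the reads at a site are treated
as a sample of `m` alleles: per-site heterozygosity
`pi = 2k(m-k)/(m(m-1))`, Watterson contribution `1/a1(m)` per segregating
site, and Tajima's D from the window sums with the 1989 normalising
constants evaluated at sample size `m`. This subsampling estimator
replaces pooled-sequencing bias-correction formulas; it does not apply a
finite-pool-size correction, so absolute levels of `pi` and `theta` are
interpretable relative to the fixed coverage `m`, and D — a normalised
shape statistic — is the quantity we rely on. Windows are physical
200-kb tiles anchored at position 1 (the terminal window keeps its true
span); D is reported only where a window has at least four segregating
sites. Genome-wide D per population is the mean over windows (the
alternative — a single D from the pooled genome-wide frequency spectrum —
is not computed); a one-sample t-test locates it against zero, and a
two-sided Mann–Whitney U test compares the per-population genome means
between regimes.

# Effective population size

Under drift plus pool-seq sampling, the variance of replicate
frequencies around the founder frequency `p0` after `t` generations is

    Var(p) = p0 (1 - p0) [1 - (1 - C)(1 - 1/(2 Ne))^t]

with `C` the mean across populations of `C_j = 1/(2S) + 1/R_j + 1/(S R_j)`.
The placement of `(1 - C)` makes the model reduce to pure sampling
variance `p0(1-p0) C` at `t = 0`, which is the stated role of `C`.
Because no sequence data exist for the base population, `p0` is estimated
as the mean frequency across all 12 populations at time `t`; each
regime's variance therefore uses the denominator `n - 0.5`, reflecting
the half degree of freedom each regime contributes to that mean. Solving
for `Ne` gives the per-SNP estimator implemented in
`estimate_ne_per_snp()`; SNPs whose observed variance falls below the
sampling floor (or above `p0(1-p0)`) are non-invertible and are excluded
from the regime medians rather than clamped, with their count reported.

Estimation (`estimate_ne()`) is restricted to putatively neutral sites
supplied as an annotation table (e.g. short-intron SNPs), with coverage
≥ 10 everywhere and mean frequency in [0.4, 0.6] — asymmetric SNPs bias
the estimator upward. Medians are reported separately for the autosome
arms and the X. Regime differences are tested by re-splitting the 12
populations 100 times into two mixed groups of 3 Selected + 3 Control
populations (`ne_randomization_test()`), with the `+1`-corrected
empirical p-value, so `p` can never be exactly zero. On synthetic drift
data the estimator recovers the simulated `Ne` within a few percent at
the median; estimating `p0` from time-`t` data leaves a mild downward
bias in the among-replicate variance that the `n - 0.5` denominator
compensates for at this design size.

# The two-pronged candidate scan

Two complementary tests target different signatures of selection:

* **Fisher exact test** on counts subsampled to 30x and pooled within
  regime (180 reads per regime) — sensitive to mean frequency
  differences, including alleles fixed in most Selected populations but
  lost from one by drift. The two-sided p-value enumerates the
  hypergeometric point probabilities not exceeding the observed one
  (the same convention, including the `1 + 1e-7` relative slack, as
  `stats::fisher.test`, against which the implementation is verified to
  1e-12).
* **Binomial mixed model** at native coverage: alternate reads out of
  `R_j` with a regime fixed effect and a population random intercept
  that absorbs drift overdispersion, tested by a likelihood-ratio test
  against chi-squared(1). With one observation per population the
  marginal likelihood factorises into 12 one-dimensional integrals,
  which the package evaluates by adaptive Gauss–Hermite quadrature
  (recentred at each conditional mode, 12 nodes by default) and
  maximises by BFGS with exact posterior-expectation gradients. The full
  model is parameterised with independent group intercepts so that the
  flat likelihood direction appearing when one regime is fixed for an
  allele stays decoupled; a regime entirely fixed for one allele
  contributes a likelihood factor of 1 and drops out analytically. Fits
  agree with `lme4::glmer` (nAGQ = 25) to ~1e-3 on the LRT for SNPs with
  interior optima. SNPs where 11 of 12 populations are fixed leave the
  random-intercept SD essentially unidentified; every implementation
  (including glmer) then lands on a software-specific boundary, and the
  package simply reports the fit with its convergence flag. The LRT is
  clamped at zero (the models are nested) and non-convergent fits are
  reported as missing p-values, which the FDR step treats as 1.

Neither test's p-values are uniform under the drift null — pooled counts
are overdispersed and the GLMM null is non-standard — so they are treated
as statistics and calibrated empirically: `n_perm = 5` permutations
reassign populations to two pseudo-groups of 3 Selected + 3 Control each
and re-run both tests end-to-end, including a fresh 30x subsample for the
FET (re-subsampling per permutation is a package choice; reusing one
subsample is configurable in principle but not exposed). The q-value of
an observed p is `min over Phat >= p of CDF_null(Phat)/CDF_obs(Phat)`,
clipped to `[1/(n_perm * n_SNPs + 1), 1]`; it is monotone in p by
construction. Candidates are SNPs with `q <= 0.05` in *at least one*
test (union first) whose regime mean frequency difference — unweighted
native-coverage read frequencies, since no weighting is prescribed —
exceeds 0.3 (filter second, strict inequality). A covariance-matrix PCA
of the population frequency vectors with a Welch t-test on PC1 serves as
the replicability QC.

# Linkage clusters and allele-frequency patterns

Within-regime residual correlations `r_w` (Pearson, over the 12
population residuals from their regime means) quantify joint evolution of
candidate pairs on the same chromosome arm; a SNP with zero residual
variance is flagged and assigned `r_w = 0`. Clusters are delineated by a
positional scan: neighbouring candidates join when they are closer than
200 kb and some candidate in the half-open window `(mid - 200kb, mid]`
correlates at `r_w > 0.8` with some candidate in `(mid, mid + 200kb)`;
clusters are the transitive closure of the joins. The half-open midpoint
windows make the rule deterministic at exact boundaries, and the scan is
direction-independent. Chromosome arm equals the sync chromosome label.

Candidates are then oriented by their "selected" allele (the one with
the higher Selected-regime mean) and classified: *high-frequency* —
≥ 0.75 in all six Selected populations, or in five with the allele lost
(< 0.05) from the sixth; *mid-frequency* — every Selected population in
[0.1, 0.9] with Selected mean in [0.25, 0.75]; anything else *other*,
including the case of five high populations with an intermediate sixth.
The lost threshold of 0.05 on read frequency tolerates occasional
miscalled reads at 30–46x where a strict zero would not. High-frequency
takes precedence if both rules match. Because both rules are symmetric
in the six populations, the test suite verifies the implementation
against an independent restatement on all 230,230 multisets of the
0.05-resolution frequency grid — equivalent to the full 21^6 grid up to
permutation.

The balancing-selection prediction — smaller among-replicate variance in
the regime where polymorphism is actively maintained — is tested on one
representative SNP per cluster (the member with mean closest to 0.5 in
the focal regime, retained when that mean is in [0.4, 0.6]) using a
two-sided Mann–Whitney U test on the per-SNP standard deviations
(denominator `n - 1`). Representatives de-correlate the test; using all
SNPs would pseudo-replicate linked clusters.

# Enrichment and overlap statistics

`multiset_intersection()` computes expected overlaps `N * prod(n_i/N)`
and exact p-values for the intersection of k sets from a common
background by chaining hypergeometric convolutions (conditioned on its
size, the running intersection is uniform by exchangeability, so each
new set overlaps it hypergeometrically). `snp_permutation_enrichment()`
draws candidate-sized SNP sets without replacement and maps them through
genes to categories, counting a gene once per draw ("gene mode";
SNP-mode counting is available) — permuting SNPs rather than genes
reproduces the length bias by which long genes collect more false
positive SNPs. `matched_network_randomization()` draws noncandidate gene
sets matched on functional class and gene-length decile (deciles because
the matching granularity is otherwise unspecified; the bins are returned
in the output) and compares interaction-edge counts; strata with too few
background genes relax to neighbouring length bins with a warning. All
empirical p-values use the `(1 + #{null >= obs}) / (n + 1)` convention.

# Numerical choices and test design

* All randomness is controlled by explicit seeds; seeded functions
  save and restore the caller's RNG state, and child seeds stay below
  2^31.
* Test problem sizes are chosen to make each property decisive yet quick:
  the null calibration of the scan uses ten replicates of 20,000 SNPs at
  the full design; Ne recovery uses five seeds of 1,200 neutral SNPs
  (over 500 pass the frequency filter per seed); power uses 120
  directional loci on a 2,000-SNP background; balancing-signature checks
  use 50 replicates of 48 balanced loci plus windowed contrasts.
* The acceptance script (`scripts/acceptance.R`) re-runs the same
  computations at three null replicates and writes the resulting
  quantities as JSON.

What passing these tests shows — and what it does not: the simulator
reproduces the statistical skeleton the analysis assumes (independent
replicate drift, two-stage pool sampling, block-correlated hitchhikers,
controllable selection), so the tests demonstrate internal consistency
and parameter recovery under that model. Real pool-seq data additionally
contain mapping artefacts, unequal pool contributions, base-calling
error, recombination-mediated partial linkage and demographic history
that the generator deliberately omits; conclusions about real data rest
on the filtering steps and on the permutation-based calibration, not on
the simulator.
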