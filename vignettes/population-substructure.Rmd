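---
title: "Detecting fine-scale population substructure with the V-matrix transformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fine-scale population substructure with the V-matrix transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaga)
```

## The problem

In many species — and acutely so in humans — the overwhelming share of
genetic variation lies *within* populations rather than between them. When
subpopulations have diverged only recently or exchange migrants, the
between-population signal in a matrix of pairwise genetic distances is a
few percent of the total, and clustering methods that consume those
distances directly struggle to recover sampling structure. This package
implements a model-free pipeline that first *transforms* the distance
matrix so that within-population variation largely cancels, and then
searches for the partition of individuals that maximizes the
among-population component of an AMOVA decomposition.

## The T1 similarity and the distance D

For a pair of diploid individuals genotyped at M biallelic SNPs, let
$n_{01,01}$ be the number of loci at which both are heterozygous and
$n_{00,11}$ (resp. $n_{11,00}$) the number at which they are homozygous for
opposite alleles. The T1 similarity is

$$ T1 = \frac{n_{01,01}}{\,n_{01,01} + n_{00,11} + n_{11,00}\,}. $$

All other genotype patterns (shared homozygotes, homozygote/heterozygote)
are ignored. Under Hardy–Weinberg equilibrium the informative pattern
probabilities at allele frequency $p$ ($q = 1-p$) are $4p^2q^2$
(both-heterozygous) and $2p^2q^2$ (opposite homozygotes), so for two
unrelated individuals from one random-mating population
$E(T1) = 4p^2q^2 / 6p^2q^2 = 2/3$ *at every allele frequency* — no allele
frequencies need to be estimated. Relatives exceed 2/3 (a parent–offspring
pair has no opposite homozygotes at all, so its T1 is exactly 1), while
pairs drawn from diverged populations fall below it. The genetic distance
is $d_{ij} = 1 - T1_{ij}$, with the within-population expectation 1/3;
`mean_distance_to_population()` flags individuals whose mean distance to
their own sampling population exceeds that threshold.

Missing calls are handled by pairwise-complete deletion: a locus is
dropped for a pair if either call is missing. Because T1 is a ratio of
pattern counts, no imputation is defensible without frequency estimates,
and none is attempted. A pair with *no* informative locus has an undefined
distance; this raises an error naming the pair rather than silently
substituting a value, because a fabricated entry would corrupt the
transformation below.

## The V transformation

The key observation is that if individuals $i$ and $j$ belong to the same
random-mating population, their *distance profiles* to every other
individual $k$ differ only by noise: in an additive (path) decomposition,
$d_{ik} - d_{jk}$ is constant in $k$. Define

$$ V_{ij} = \operatorname{var}_k\!\left(d_{ik} - d_{jk}\right),
   \qquad k \notin \{i, j\}, $$

i.e. the variance over the $N-2$ retained differences (the two terms where
$k$ is $i$ or $j$ itself are excluded — they involve the zero diagonal and
would contaminate the variance with $d_{ij}$ itself). For a two-group
configuration with group sizes $n_I, n_J$, between-group distance $d$, and
i.i.d. Gaussian error of standard deviation $\sigma$ on every pairwise
distance, the expectations are

* within-group pair: $V = 2\sigma^2$;
* between-group pair:
  $V = \dfrac{4(n_I-1)(n_J-1)}{(n_I+n_J-2)^2}\, d^2 + 2\sigma^2$,

which reduces to $d^2 + 2\sigma^2$ at equal group sizes and to $2\sigma^2$
when either group is a singleton — a lone individual's distance to its own
population cannot be separated from the between-population distance, so
singletons contribute no detectable structure. The within-population term
$2\sigma^2$ no longer depends on how far each individual sits from its
population: the transformation *homogenizes* within-population variation
and leaves a term quadratic in the between-population distance.

`v_matrix()` computes this exactly (it uses the algebraic identity
$\operatorname{var}(x) = E[x^2] - E[x]^2$ row-wise for an $O(N^3)$
evaluation via one matrix product, and is tested against a naive
double-loop at $10^{-12}$). `v_theory_oracle()` exposes the closed forms.

### Variance convention

The default divides by the count of retained differences, $N-2$
(population convention). This is the convention under which the noise-free
equal-size identity $V = d^2$ holds *exactly*, which is how the analytic
limits are stated; the sample convention (divide by $N-3$) is available
via `convention = "sample"`. Note that under the population convention the
*expected* within-pair value in noise is $\frac{N-3}{N-2}\,2\sigma^2$; the
tests that check the $2\sigma^2$ limit to 5% therefore use two groups of
25 ($N = 50$), where the finite-size factor $47/48$ biases the mean by
about 2%, comfortably inside the band. This group size was fixed from that
analytic argument when the test was designed.

## AMOVA decomposition

For a partition of the $N$ individuals into groups $g$ with sizes $n_g$,

$$ SS(T) = \frac{1}{2N}\sum_i\sum_j \delta^2_{ij}, \qquad
   SS(WP) = \sum_g \frac{1}{2n_g}\sum_{i,j\in g}\delta^2_{ij}, \qquad
   SS(AP) = SS(T) - SS(WP), $$

and the sensitivity metric used throughout is $SS(AP)/SS(T)$.

**Entries are consumed as already-squared distances by default**
(`square_entries = FALSE`). V is variance-scaled — already quadratic in
distance, as the $d^2$ limit above shows — and classical AMOVA consumes
squared Euclidean distances. All D-versus-V comparisons in this package
run both matrices through the identical decomposition, so the two
pipelines differ only in the transformation. Setting
`square_entries = TRUE` squares the entries first.

Two numerical notes. A negative $SS(AP)$ at round-off scale (within
$10^{-9}$ relative) is clamped to zero. For an *arbitrary* symmetric
matrix and a mismatched partition, $SS(AP)$ can be genuinely negative
(such a matrix need not embed in any Euclidean space); that value is kept,
so the decomposition always conserves $SS(T)$ exactly, and only the
reported `ratio_among` is clamped into $[0,1]$. Second, with $K$ groups
over $N$ samples the ratio for *random* labels concentrates around
$(K-1)/(N-1)$ rather than 0 — a baseline worth keeping in mind when
reading absolute percentages (the near-panmixia simulations below sit at
this baseline, not at zero).

## The genetic algorithm

`optimize_partition()` searches assignments of $N$ individuals to at most
$K$ clusters for the partition maximizing $SS(AP)$ (equivalently
minimizing $SS(WP)$, since $SS(T)$ is fixed). $K$ is an upper bound —
empty clusters are legal throughout, so the effective number of clusters
is learned. The encoding is an integer assignment vector; the contract is
fixed by the fitness, not the encoding.

Operators: binary tournament selection; a grouping-style *subcluster-swap*
crossover — one non-empty cluster chosen from each parent is imposed on
the other, and displaced members (recipients of the imposed label that are
not members of the imposed cluster) fall back to their label in the donor,
which is guaranteed distinct, making the operator deterministic given the
cluster choice and a fixed point for identical parents; per-sample uniform
mutation at rate $1/N$; single-elite survival (the fitness trace is
therefore nondecreasing); stop after 100 stagnant generations or 2000
generations. Fitness values are cached under a canonical relabelling of
the partition (clusters numbered by first appearance), so label-permuted
duplicates cost nothing. The within-group sum is evaluated in compiled
code. Defaults follow standard genetic-algorithm practice for grouping
problems; correctness is established against exhaustive enumeration on
instances with $N \le 10$, where the algorithm recovers the global optimum
in well over 80% of seeded runs and can never exceed it.

`gaga()` wraps the whole pipeline — genotypes → D → V → GA → AMOVA — into
a single fit returning a classed object with `print()`, `summary()` and
`plot()` (fitness trace) methods, plus label-based evaluation when the
sampling origins are known.

## Evaluation statistics

* **BOM%** — the share of individuals whose nearest neighbour under the
  matrix (best overall match) carries their own population label. Ties on
  the row minimum are broken by smallest sample index and counted;
  real-valued matrices essentially never tie, but degenerate synthetic
  fixtures can. BOM depends only on the ranking of entries, so it is
  invariant under any strictly increasing transform of the matrix.
* **Cramér's V** — $\sqrt{\chi^2 / (N(k-1))}$ on the clusters-by-
  populations table, $k$ the smaller dimension, no continuity correction
  (the statistic is used, not the test), defined as 0 when $k = 1$.
* **Informativeness for assignment** $I_n$ — Rosenberg's entropy measure
  between two populations' cluster-frequency vectors, with $0\ln 0 = 0$
  and natural logarithms, so the perfect-separation bound is $\ln 2$.
  (The bound stated as "log(2)" is only consistent with the natural-log
  convention, which fixes the base.) `min_in_per_population()` reports
  each population's minimum $I_n$ against all others — its separation
  from its *closest* counterpart — and the mean of those minima.

## Simulators

Three generators supply data with known structure:

* **Additive graph model** (`simulate_graph_model()`): three parental
  populations around a central group vertex plus one admixed population,
  10 individuals per population; individual-to-population edges drawn from
  $U(0.5, 1)$, population-to-group edges from $U(m^*, 1)$ or $U(0, m^*)$
  with $m^*$ the minimum individual edge (larger/smaller regimes), each
  length either shared (constant regimes) or redrawn per edge/individual;
  pairwise distance = path sum + $N(0, 0.05^2)$ noise. The admixed
  population's cross-distances average the two parental paths 50/50 (the
  mixing weight is configurable; equal weights are the neutral choice
  where no value is prescribed). The eight regime combinations are the
  conditions under which the V-beats-D contrast is asserted: at 100
  replicates per combination, the V-based $SS(AP)/SS(T)$ exceeds the
  D-based one in at least 99% of replicates.
* **2-D stepping stone** (`simulate_stepping_stone()`): 25 demes on a
  5×5 grid, 10 diploids sampled per deme. Deme allele frequencies start
  at a common ancestral draw $U(0.05, 0.95)$ per SNP and evolve forward:
  each generation a fraction $m$ of a deme is replaced by an even mixture
  of its rook neighbours, then binomial drift at $2N_e$ gametes
  ($N_e = 100$, 200 generations). Differentiation grows as $m$ shrinks.
* **Sequential split** (`simulate_sequential_split()`): a serial-founder
  chain — every $t$ generations the youngest deme splits, the new deme
  founded at $N_e/s$ after the $s$-th split, floored at $N_e/10$
  ($N_e = 500$ by default here, because the 24 successive founder
  bottlenecks accumulate drift multiplicatively; without the floor the
  late demes fix at essentially every locus, and within-deme pairs lose
  all informative genotype patterns). Differentiation grows with $t$.

The two demographic generators are *frequency-model* backends: forward
Wright–Fisher dynamics on deme allele frequencies with independent SNPs
(as if one SNP were sampled per recombinationally independent 50-kb
fragment), not a coalescent simulation of sequences. The backend is
recorded in the output's `backend` attribute. What they reproduce is the
distributional contract that matters for the method — differentiation
monotone in the structure parameter, HWE within demes, independent loci.
What they do *not* reproduce: linkage disequilibrium, ascertainment bias,
recombination within fragments, mutation during the simulated epoch, or
realistic site-frequency spectra. Passing tests on these generators
therefore demonstrate the behaviour of the *matrix machinery* under known
structure, not robustness to every property of real SNP-array data.
`simulate_balding_nichols()` provides the standard one-step
Beta-distributed deme-frequency model for fixture work, and
`simulate_hwe_population()` / `mendelian_offspring()` generate the
unrelated and parent–offspring fixtures for the T1 expectations.

A ceiling effect is worth noting: on strongly structured data the V-based
$SS(AP)/SS(T)$ saturates near 100%, so along a structure gradient its
curve plateaus (and can wobble by replicate noise at the top) while the
D-based curve is still rising. Trend assertions therefore use rank
correlation over replicated grids rather than strict monotonicity of the
saturated statistic.

## MDS and model-based clustering

`classical_mds()` double-centers $-\tfrac12 \delta^2$ and
eigendecomposes; if the smallest eigenvalue is negative (the matrix is
non-Euclidean — V matrices usually are), the Cailliez additive constant is
applied to the off-diagonal dissimilarities and the scaling recomputed, so
no retained eigenvalue is negative. Explained variance per dimension is
reported against the positive eigenvalue mass. `gmm_bic_cluster()` fits
Gaussian mixtures over a range of component counts on the first 10
dimensions (the standard choice for this analysis) via `mclust`, selecting
the model by BIC under mclust's higher-is-better sign convention; mixture
sizes whose fits fail are skipped with a warning, never a crash.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state, so identical configurations reproduce identical outputs. The
shipped test and acceptance workloads use desk-scale problem sizes chosen
to make every Monte-Carlo band comfortably wide: 50 unrelated pairs at
100,000 SNPs for the T1 expectation, 800 graph-model replicates, 5,000
SNPs and 25 demes for the demographic gradients, 1,000 random instances
for the AMOVA conservation check, and 20 exhaustively-verifiable GA
instances. The empirical results reported for the 2,457-individual
European SNP-array dataset in the literature are not reproduced here: that
genotype set is not redistributable, so validation rests on the analytic
limits and the simulation contrasts above.

## Known limitations

* T1 requires diploid biallelic genotypes; haploid or polyploid data are
  out of scope, as are allele-frequency-based distances.
* The V transformation needs at least two individuals per population to
  detect it (the singleton limit above), and at least 4 individuals total.
* The GA provides no automatic choice of $K$; take it from prior
  knowledge or from the BIC table of `gmm_bic_cluster()`.
* LD pruning, HWE filtering and imputation are deliberately external:
  feed the package a pruned, cleaned genotype matrix.
* `mclust`'s full 14-model family is used as-is; which covariance model
  BIC selects on a given dataset is data-dependent and no equivalence
  with any particular published clustering run is claimed.
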