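---
title: "Simulating sequence cohorts with disease and quantitative trait models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sequence cohorts with disease and quantitative trait models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcohort)
```

## Purpose

`seqcohort` simulates sequence-level genotypes together with phenotypes —
dichotomous disease status or a quantitative trait — for two study designs:
three-generation pedigrees ascertained on affected third-generation
siblings, and unrelated case-control samples.  Its intended use is the
evaluation of statistical methods for next-generation-sequencing
association studies: estimating power for a planned design, or checking
the type I error of a new rare-variant test on data whose generating model
is fully known.

The simulation pipeline has four layers:

1. a **haplotype pool**: a finite population of phased 0/1 sequences whose
   sites are grouped into recombination-free blocks;
2. a **recombination map** giving the recombination fraction between
   adjacent block centers;
3. a **phenotype model**: logistic or population-attributable-risk (PAR)
   penetrance for disease, or a variance-decomposition model for a
   quantitative trait;
4. a **cohort sampler** that gene-drops pedigrees or draws unrelated
   individuals, applies ascertainment, and writes PLINK ped/map files.

## The haplotype pool

Founders are drawn by random mating from a pool of `n` haplotypes.  The
built-in generator simulates each block as an independent, constant-size
neutral coalescent genealogy (Hudson's algorithm): inter-coalescence times
while `k` lineages remain are exponential with rate `k(k-1)/2` (in units
of `2N` generations), and each branch of length `L` receives
`Poisson(theta L / 2)` infinite-sites mutations, where `theta = 4Nu` is
the per-block scaled mutation rate.  Two consequences matter for rare-variant
work:

* the expected number of segregating sites is Watterson's
  `theta * sum_{i<n} 1/i`, which the test suite verifies;
* the site-frequency spectrum is the neutral `1/i` spectrum, so large
  pools are heavily enriched for variants with MAF below 0.01 — the raw
  material for rare-variant association studies.

Pools can also be ingested from plain 0/1 matrix files, phased VCF, or the
text output of coalescent sequence simulators (any line whose
non-whitespace characters are all 0/1 is taken as a haplotype).
Monomorphic columns are dropped with a message: they carry no information
and would poison MAF-based causal-site selection.

**What the generator does not emulate.**  Blocks are mutually independent;
there is no ancestral recombination linking them, no demography (growth,
bottlenecks, migration), and no selection.  Real sequence data have
LD decaying smoothly with distance and an excess of very rare variants
relative to the constant-size neutral spectrum.  Tests passing on
generated pools therefore validate the machinery (penetrance, sampling,
file formats, test calibration), not any claim about a particular human
population; for population realism, feed the package a pool produced by a
demographically calibrated simulator.

## Recombination

There is no recombination within a block.  Between adjacent blocks `i`
and `i+1` a meiosis switches parental haplotype with probability
`theta_i`, independently across intervals (no crossover interference).
Map distances use Haldane's function `d_cM = -50 log(1 - 2 theta)` and its
inverse; the test suite checks the round trip to 1e-12 and the additivity
of distances under the composition
`theta_12 = theta_1 + theta_2 - 2 theta_1 theta_2`.

Hotspot tables (`chrom start end rate_cM_Mb`, 1-based inclusive) convert
to interval fractions by summing `rate x width / 1e6` cM over the hotspots
whose midpoint falls between two block centers.  The width used is the
hotspot's own extent, which conserves the table's total map length; a
hotspot spanning a center is attributed to the interval containing its
midpoint.  A recombination fraction can never exceed 0.5: configurations
asking for more are rejected with a suggestion to use 0.5, which marks a
chromosome break (unlinked).

**Chromosomes and linkage equilibrium.**  A founder draws one independent
pool row per chromosome rather than a single row for the whole genome.
In a finite pool, reusing one row across unlinked chromosomes creates
spurious identity disequilibrium: conditioning cases on causal genotypes
then drags along the null-chromosome content of the carrier rows, and we
measured type I error inflation to roughly 0.10 at nominal 0.05 in the
cross-chromosome null experiment.  Random mating over many generations
puts unlinked chromosomes in linkage equilibrium, which the
per-chromosome draw implements exactly; within a chromosome the pool's
full haplotype (LD) structure is preserved.

## Disease models

Both models share the genotype coding `k`: the number of risk alleles
(0/1/2) under the additive mode, presence/absence of a risk allele (2/0)
under the dominant mode, and presence/absence of the homozygous risk
genotype (2/0) under the recessive mode.  The risk allele is the derived
allele by default (a switch selects the minor allele instead).

**Logistic (prevalence-driven) model.**
`P(affected | X) = expit(alpha + B X)` with per-locus log odds ratios `B`.
The intercept is `alpha = logit(f0)`, the log odds of the baseline
penetrance.  When the user specifies a target prevalence `K` instead,
`solve_alpha()` bisects `alpha` in `[-20, 20]`: the prevalence estimate at
each iterate is the mean penetrance over a single fixed Monte Carlo
sample of 200,000 random-mating genotype draws, reused across iterations
(common random numbers), so the estimate is a deterministic, continuous,
strictly increasing function of `alpha` and bisection terminates with
`|K_hat - K| < epsilon` (default 0.001).  The default sample size keeps
the Monte Carlo standard error of `K_hat` near 0.0007 for `K` around 0.1,
well under the default tolerance.  Unreachable targets (e.g. `K` below
the floor attainable at `alpha = -20`) raise an error reporting the
attainable range.  The same coding drives dominant and recessive variants
of the model, so a coefficient in `B` always means "log odds per coded
unit".

**PAR model.**  The user fixes the baseline penetrance `f0` and a total
population attributable risk; each locus's share `PAR_i` (equal split, a
uniform-simplex random split, or explicit values) converts to a genotype
relative risk

    GRR_i = PAR_i / ((1 - PAR_i) R_i) + 1,

where `R_i` is the risk allele frequency — so with equal PAR shares,
rarer variants get larger effects.  Penetrance is
`f0 prod_i GRR_i^{k_i} / (1 - f0 + f0 prod_i GRR_i^{k_i})`, algebraically
a logistic model with slopes `log GRR_i`.  Protective loci invert their
relative risk.  The dominant-mode heterozygote receives `GRR^2` (coded
`k = 2`), exactly as the model is written; a compatibility switch codes it
`k = 1` for comparison with tools that use the single-dose convention.
The model's prevalence is implied rather than specified;
`population_prevalence()` estimates it by Monte Carlo with a reported
standard error.

## Quantitative traits

A trait decomposes as `Y = mu + sum_j G_j + P + E` with
`P ~ N(0, V_poly)` and `E ~ N(0, V_P - sum_j V_Pj - V_poly)`; infeasible
decompositions are rejected when the specification is built, not at
sampling time.  Each QTL `j` explains a fraction `f_j` of the total
variance `V_P`.  Writing `p` for the minor-allele (A1) frequency, the
genotypic value is `a_j = sqrt(V_Pj / D)` with denominator `2pq`
(additive), `8pq^3 + 4p^2q^2` (dominant) or `8p^3q + 4p^2q^2` (recessive),
and the genotype means for A1A1/A1A2/A2A2 are `(a, 0, -a)`, `(a, a, -a)`
and `(a, -a, -a)` respectively.  The denominators are exactly the
Hardy-Weinberg variance of those three-point means divided by `a^2`, so
`Var(G_j) = V_Pj` holds as an identity; the test suite asserts it to
1e-10 for all modes and random frequencies.

One reading of the model treats `G_j` as noisy around its genotype mean
with variance `V_Pj` per individual.  Implemented literally, that
double-counts the per-QTL variance (the total would exceed `V_P`), so by
default `G_j` is the deterministic genotype mean and `V_Pj` is understood
as the population variance induced by genotype frequencies.  The literal
reading remains available behind the `literal_gj_noise` switch for
comparison.  Two further conventions: the QTL contribution is not
centered (the population mean of `G_j` is `a(p - q)` under additivity, so
`mu` is the general mean before genotypic displacement), and the variance
decomposition assumes QTL in linkage equilibrium — QTL picked from one
block in LD will push `Var(Y)` above `V_P`.

## Cohorts, ascertainment, and the fast case sampler

A pedigree has 12 members: two founder couples, the father and mother
(each a child of one couple, produced by meiosis), and six full siblings
in generation 3 (the sibship size is configurable, which changes the
total; no married-in spouses are simulated).  Affection is assigned to
every member by comparing penetrance with a uniform draw; ascertainment
keeps families with at least `s` affected third-generation siblings
(generations 1-2 never enter the rule).  Rejection sampling aborts with a
diagnostic after 1000 consecutive failures per family slot.

Unrelated cases and controls are drawn directly as founder pairs: under
random mating, a third-generation child's marginal block-level genotype
distribution equals the founder distribution, so discarding a whole
simulated family per individual would change nothing but the runtime.
The literal procedure (`faithful_thirdgen = TRUE`) is kept for
comparison, and a test checks that the two agree.

Rejection sampling of cases costs `1/K` penetrance draws per case, which
is painful for rare diseases.  The fast sampler instead (1) rejection
samples a pilot of 100 cases, (2) tabulates the empirical conditional
distribution of the multilocus causal genotype `X` given affection, then
(3) for each case draws `X` from that table, picks a phase assignment
uniformly among assignments consistent with at least one pool haplotype
pair, and draws each haplotype uniformly from the pool haplotypes
matching its causal-site allele vector.  No penetrance is evaluated after
the pilot (the suite asserts the count is zero), so runtime is
independent of prevalence.  The price is the pilot's sampling error: with
100 pilot cases the conditional table is an estimate, and genotype
distributions of fast and rejection cases agree only within that error
(the suite compares them by chi-square at a 10,000-case pilot, where the
error is negligible).

Every stochastic operation draws from a keyed substream of a master seed,
so outputs are reproducible and, because each family or replicate owns
its substream, identical for any number of workers.

## The variance-component score test

The validation harness needs an independent association test, so the
package implements the standard weighted variance-component score test
for a region: `Q = (y - ybar)' G W G' (y - ybar)` with
`W = diag(w_j^2)`, `w_j = dbeta(MAF_j, 1, 25)` (the published
rare-variant default).  Under the null, `Q` is a mixture
`sum_j lambda_j chi2_1` with `lambda_j` proportional to the eigenvalues
of the centered, weighted genotype cross-product.

Three p-values are offered.  The default is the saddlepoint
(Lugannani-Rice) tail of the mixture, chosen after a direct comparison on
Monte Carlo mixtures: at a true tail probability of 0.05 it returned
0.049 and at 0.01 it returned 0.0095, whereas the moment-matched scaled
chi-square (also available as `p_method = "moment"`) drifts by one to two
percent in the bulk and is visibly non-uniform under the null.  A plain
adaptive-quadrature inversion of the characteristic function was tried
and rejected: under fast oscillation (large `Q`) it can converge silently
to wrong values.  The third option is a phenotype-permutation p-value,
exact by construction, used in the suite as the calibration oracle.  The
saddlepoint solver falls back to the moment approximation in the single
degenerate situation where `Q` sits at the mixture's mean.

## Problem sizes in the validation runs

The replicate harness reproduces two published figures: the power of the
score test on a 329-site causal region (30 causal loci with MAF < 0.01,
`f0 = 0.1`, total PAR 0.1, additive) and its type I error on an unlinked
355-site region, each with 1000 cases and 1000 controls.  Each replicate
is a complete simulator run — a fresh coalescent pool (2000 haplotypes,
`theta = 70` per block, trimmed to the two region sizes), fresh causal
sites, fresh cohort — mirroring how such a tool is actually invoked per
dataset; power and size estimates therefore average over
sequence-generation randomness as well as sampling noise.  The packaged
test suite runs a 300-replicate smoke version of this experiment and
1000-pool Watterson checks; the acceptance script runs the full 1000
replicates.  The implied-prevalence check uses 200,000 Monte Carlo
genotype draws, putting its standard error near 0.0007, an order of
magnitude below the tolerances of interest.

## Known limitations

* The built-in pool generator is deliberately minimal (constant
  population size, independent blocks); import a pool for realistic
  demography or LD between blocks.
* The fast case sampler requires all causal loci on one chromosome
  (the rejection sampler has no such restriction).
* One inheritance mode applies to all causal loci of a model; per-locus
  modes, gene-gene interaction, covariates and liability thresholds are
  out of scope.
* Pedigree topology is fixed apart from the sibship size; no twins,
  half-sibs, or user-drawn structures.
* The score test handles binary phenotypes without covariates — it is a
  validation oracle, not a general analysis tool.
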