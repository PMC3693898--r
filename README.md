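# seqcohort

Simulation of sequence genotypes and phenotypes in families and
case-control cohorts, for power and type I error studies of
next-generation-sequencing association methods.

Statistical tests for rare variants — burden tests, variance-component
score tests and their relatives — are usually evaluated on simulated
data in which the generating model is fully known.  `seqcohort` produces
such data end to end: it builds (or ingests) a pool of phased haplotypes
with many rare variants, assigns dichotomous disease status or a
quantitative trait under user-specified genetic models, samples either
three-generation pedigrees with affected-sibling ascertainment or
unrelated case-control sets, and writes standard PLINK ped/map files.
A weighted variance-component score test and a replicate harness are
included for calibrating power and type I error on the simulated data.

## Models

**Haplotype pool.** A per-block neutral coalescent (constant population
size, infinite sites, scaled mutation rate θ per block) generates a
binary haplotype matrix whose expected segregating-site count is
Watterson's θ·Σ 1/i and whose site-frequency spectrum is enriched for
rare variants.  Pools can also be read from 0/1 matrix files, phased
VCF, or coalescent-simulator text output.  Sites are grouped into
recombination-free blocks; meioses switch parental haplotype between
blocks with interval-specific recombination fractions θᵢ, related to map
distance by Haldane's function d(cM) = −50 log(1 − 2θ).

**Disease.** Either a logistic penetrance
P(aff │ X) = expit(α + B·X), with α solved by bisection so the
population prevalence matches a target K to within ε = 0.001, or a
population-attributable-risk model with baseline penetrance f₀ and
per-locus relative risks GRRᵢ = PARᵢ/((1 − PARᵢ)Rᵢ) + 1, so that equal
PAR shares give rarer variants larger effects.  Additive, dominant and
recessive codings; protective loci invert their effect.

**Quantitative trait.** Y = μ + Σⱼ Gⱼ + P + E, where each QTL explains a
chosen fraction fⱼ of the phenotypic variance V_P through a genotypic
value aⱼ = √(V_P fⱼ / D) (D = 2pq, 8pq³+4p²q², or 8p³q+4p²q² by mode),
P ~ N(0, V_poly) and E absorbs the remainder.

**Fast case sampler.** Cases can be drawn from the empirical
distribution of causal genotypes in a small pilot of rejection-sampled
cases, then phased onto consistent pool haplotypes — no penetrance
evaluations after the pilot, so runtime is independent of prevalence.

## Worked example

```r
library(seqcohort)

pool <- generate_block_pool(n_haplotypes = 2000, n_blocks = 2,
                            theta_per_block = 40, chrom = c("1", "2"),
                            seed = 42)
pool
#> <haplotype_pool> 2000 haplotypes x 607 sites in 2 block(s) on 2 chromosome(s)

causal <- select_causal_sites(pool, n = 30, maf_range = c(0, 0.01),
                              blocks = 1, seed = 42)
spec <- disease_spec(pool, causal, model = "par", mode = "additive",
                     f0 = 0.1, par_total = 0.1)
population_prevalence(pool, spec, n_draws = 200000, seed = 42)
#> implied prevalence: 0.1142 (SE 0.00012)
```

Thirty rare causal loci sharing a total PAR of 0.1 lift the prevalence
from the baseline 0.10 to about 0.114.  Family and case-control samples:

```r
rmap <- fixed_map(0.5, 2)   # two unlinked blocks
rmap$centers_bp <- pool_block_centers(pool)$center_bp
rmap$chrom <- pool_block_centers(pool)$chrom

fams <- simulate_families(pool, rmap, disease = spec, n_families = 100,
                          s = 1, seed = 42)
attr(fams, "acceptance_rate")
#> 0.51    # about half of simulated families have >= 1 affected sib

cc <- simulate_case_control(pool, spec, n_cases = 1000, n_controls = 1000,
                            fast_mode = TRUE, seed = 42)
vc_score_test(cohort_genotypes(cc, pool, which(pool$sites$block == 2)),
              cc$members$aff)
#> p = 0.323      # unlinked region: no association
vc_score_test(cohort_genotypes(cc, pool, which(pool$sites$block == 1)),
              cc$members$aff)
#> p = 5.35e-04   # causal region detected

write_plink(fams, pool, rmap, "families")
#> families.ped, families.map  (e.g. "1  chr1_b1_2  0  2")
```

A command-line wrapper (`inst/cli/seqcohort.R`) exposes the same
pipeline as `pool generate|convert`, `simulate family|cc` and `power`
subcommands driven by flags or a reusable `key = value` control file;
see `?run_cli`.

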