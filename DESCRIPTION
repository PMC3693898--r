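Package: seqcohort
Title: Simulation of Sequence Genotypes and Phenotypes in Families and
    Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates sequence-level genotypes together with dichotomous
    disease status or quantitative traits, for three-generation pedigrees
    with affected-sibling ascertainment and for unrelated case-control
    samples.  Founder haplotypes are drawn under random mating from a
    haplotype pool, generated internally by a per-block neutral coalescent
    or read from plain 0/1 matrices, phased VCF, or coalescent-simulator
    output.  Disease status follows either a logistic penetrance model with
    an intercept solved to match a target prevalence, or a population
    attributable risk (PAR) model that converts per-locus PAR into genotype
    relative risks.  Quantitative traits decompose a user-specified
    phenotypic variance into per-QTL, polygenic and environmental
    components.  Crossovers between recombination-free blocks use
    hotspot-derived or fixed recombination fractions, converted to map
    distances with Haldane's mapping function.  Cohorts are written as
    standard PLINK ped/map files, and a weighted variance-component
    rare-variant score test with a replicate harness supports power and
    type I error studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
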