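---
title: "Simulating SpeedGS breeding programs for allogamous crops: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating SpeedGS breeding programs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`speedgs` is a stochastic simulator for breeding programs of outcrossing
forage crops, built around tall fescue, an allohexaploid. It answers a
design question breeders face today: how much genetic gain does combining
genomic selection (GS) with speed breeding (SB) buy over a conventional
phenotypic program, and what does it cost in inbreeding? This vignette is
the package's own account of the models it implements, the parameters that
matter, and the design choices made where the problem left them open.

## The base population

Tall fescue carries three ancestral diploid subgenomes. Because the crop
behaves cytogenetically like a diploid with 21 independent chromosomes, the
simulator treats each chromosome as an independent diploid chromosome with
two haplotypes per plant and biallelic loci, so allelic dosage is 0/1/2
everywhere. `run_forward()` replays the demographic history: a monomorphic
common diploid ancestor accumulates variation under mutation–drift; three
speciation events fork the three diploid progenitors; the first two
hybridize into a tetraploid; the tetraploid and the third diploid form the
hexaploid, which then evolves until mutation–drift equilibrium. Each
generation applies random mating between distinct parents (no selfing —
the species is self-incompatible), Poisson(λ = 1) crossovers per 100 cM
chromosome with uniformly placed breakpoints and no interference, and
per-locus allele-flip mutation at rate µ. The allele-flip (two-allele)
mutation model is chosen to match the biallelic equilibrium expectation
E(He) = 4Neµ/(8Neµ + 1); at the full-scale parameters Ne = 10⁴ and
µ = 10⁻⁵ this gives 0.222. LD decays as E(r²) = 1/(2 + 4NeC) + 1/n with C
in Morgan.

Two interpretive choices deserve a note. Newly formed taxa (speciation
forks and both hybrids) start from a founder sample (one tenth of the
population by default) and grow geometrically back to full size over the
expansion window — "exponential expansion" realized as a constant
per-generation growth factor. Hybrids are amphidiploids: each hybrid
founder receives, for every parental chromosome set, two recombined gametes
from two distinct parents of that population, so each chromosome stays an
independent diploid chromosome and subgenomes never exchange material. The
ancestor starts monomorphic; all standing variation is mutation–drift
equilibrium variation, which is what the equilibrium diagnostics (the
`he_trace` attribute) certify before the population is used.

Twenty founder cultivars are derived by sampling plants from the base
population and running 100 closed generations of random mating without
mutation, mimicking the independent histories of commercial material.

## Scale profiles

The full-scale profile (`preset = "full"`: 10⁴ plants, 21 × 10⁵ loci,
~10⁵ generations, 10⁵-SNP panel) is cluster-sized. The `"desk"` profile
runs the identical code path at reduced sizes: 300 plants, 3 chromosomes ×
1,000 loci, a proportionally compressed event schedule ending at
generation 2,000, and µ rescaled so the population-scaled mutation
parameter 4Neµ = 0.4 is preserved — hence the desk equilibrium
heterozygosity has the same expectation (0.222) as the full-scale run, and
LD decay differs only through the explicit Ne in the closed form. Trait
architecture scales to 200 QTL per trait (100 shared), the panel to 500
SNPs, and the breeding-program cardinalities by roughly one fifth (e.g.
topcross 600, initial SpeedGS population 200, candidate pairs capped at
the top 500). All tests and the bundled analyses use the desk profile;
sizes appear in `base_preset()` and `scheme_config()` and nothing else
changes between profiles.

## Trait architecture and correlated QTL effects

Five traits are bred simultaneously: heading date (HD, h² = 0.7), forage
yield (FY, 0.3), seed yield (SY, 0.4), quality (Q, 0.3) and persistency
(Per, 0.1). Each has 1,000 additive QTL sampled from loci with base MAF >
5%; FY, SY and HD share a 500-locus pleiotropic block; FY–SY and FY–HD
genetic correlations are 0.2 and 0.3. HD and Q have mixed architectures:
20 (HD) and 100 (Q) large-effect QTL explain e = 50% of the effect
variance. Small effects are N(0, 1); large effects are N(0, m) with

  m = e (n − l) / (l (1 − e)),

the unique variance making l large-effect QTL carry a fraction e when the
n − l small effects have unit variance (m = 49 for HD, 9 for Q).

Standard multivariate-normal tricks cannot impose a correlation on columns
drawn from these unequal-variance mixtures, so the package implements the
Cholesky-rescaling method in `correlate_effects()`: with S the empirical
column covariance of the raw matrix R and S = LLᵀ, the rescaled matrix
RS = R L⁻ᵀ has exactly identity empirical covariance, and RS Dᵀ with
C = DDᵀ has exactly the empirical correlation C. Because the construction
uses empirical covariances it is exact to machine precision at any sample
size, which the tests pin down on hand-sized instances.

Where the correlation is imposed was genuinely open: applying C to the
full 1,000 × p matrix would mix the HD mixture columns with unit-normal
columns and dilute the large-effect class. The package instead imposes the
correlation block-wise on the 500 shared loci, with the within-block
correlation inflated by the inverse of each trait's shared-block variance
share (computed with per-locus 2p(1−p) weights at the assigned QTL), so
the genome-wide genetic correlation lands on target while HD's and Q's
large-effect classes — kept on private loci — survive intact. The realized
TBV correlations and the preserved ~50% variance share are verified
empirically in the test suite, not assumed. If a requested correlation
cannot be carried by the shared block (inflation ≥ 1 or a non-positive-
definite block matrix), the architecture is rejected with guidance rather
than silently attenuated.

TBVs are dosage-weighted effect sums. Phenotypes add independent normal
errors per trait with σe² = Var(TBV)(1 − h²)/h² refreshed from each
cycle's initial cohort, so realized heritability stays nominal as genetic
variance erodes. Plot-level phenotypes use the plot-mean TBV plus one
deviate whose variance keeps plot-level h² equal to the single-plant h² —
the study gives only single-plant heritabilities, and this choice keeps
selection intensity comparable across stage types.

## The breeding schemes

The phenotypic program (PS, 11-year cycle) is: crossing (10 random
disjoint cultivar pairs × 5 F1 populations × 100 seeds → 5,000 plants);
topcross (discard earliest 20% by HD, draw 100 at random from the SY top
60%); small plots (500 half-sib seeds per selected plant; top 40 plots by
the equal-weight standardized FY+Per index; 25 clones from each plot's top
80%); single rows (1,000 rows, top 500 by Q); synthetics (50 groups of 10
HD-adjacent rows); field trial (top 20 large plots by FY+Per become the
next cultivars). The four SpeedGS scenarios replace crossing+topcross with
a one-year SB stage and omit zero or more middle stages (S1 9 y, S2 6 y,
S3 7 y, S4 4 y); each SB round genotypes 1,000 candidates, predicts GEBVs,
scores all 499,500 parent pairs by parent-average index (weights Per 0.35,
FY 0.25, SY 0.15, Q 0.15, HD 0.1 on cohort-standardized GEBVs), draws the
crossing scheme (1,000 × 1 or 100 × 10) from the top 10,000 pairs and
produces the next cohort by meiosis without mutation.

Gaps the description leaves open were closed as follows, each verified to
reproduce the stated stage cardinalities. Heading-date orientation: larger
phenotype = later heading, so the "earliest 20%" cull removes the lowest
values. Pollen for small plots comes from the HD-surviving topcross
plants. In S1/S2 the small-plot mothers after the SB stage are the top 100
output plants by index GEBV, pollinated by the whole output cohort. Where
single-row phenotypes do not exist (S2, S4) the SY+Q selection and HD
grouping use GEBVs. Synthetics take the top `field_trial_size ×
synthetic_size` plants of their input, sort by heading date and partition
contiguously — this one rule yields 50 × 10 in PS/S1/S2, the enlarged
100-plot field trials of S3/S4, and the size-5 inbreeding variant. All
selection indices standardize within the cohort being selected; all ties
break by a seeded uniform draw. No mutation occurs during cultivar
derivation or the breeding program.

The initial SpeedGS population of cycle five is a random 1,000 of the
fifth PS cycle's 5,000 topcross seeds; later cycles cross the current
cultivars (50 crosses × 20 progeny by default; the inbreeding-mitigation
variants use 100 × 10, 200 × 5 or 1,000 × 1, drawing more distinct plants
per cultivar).

## Genomic prediction

The reference population holds pooled plot genotypes: each plot is scored
as twice the allele frequency of 20 randomly sampled member plants, a
fractional dosage in [0, 2]. It opens with the warm-up small plots (4 ×
100 at full scale) and grows by the plots each scenario genotypes (150 per
cycle for S1/S2, 100 for S3/S4). Reference plots record plot-level
phenotypes for all five traits so every trait's prediction equation can be
trained, while selection at any stage still uses only that stage's traits.
Marker effects come from Bayesian ridge regression — a Gaussian prior with
one common effect variance — fit per trait. Two paths share one contract:
a blocked Gibbs sampler (multivariate-normal effect updates, scaled-
inverse-χ² updates with 5 prior df for both variances, prior scales set
from the phenotypic variance and the trait h²) and a deterministic ridge
solve at the h²-derived variance ratio, which is the exact posterior mean
when the variances are fixed and is what scheme runs use. GEBV = Zβ̂;
accuracy is the Pearson correlation with TBV, recorded per trait, cycle
and SB round. Candidates use integer dosages and reference rows fractional
pooled dosages in the same model; allele coding is fixed at the
base-population panel and persisted so models stay comparable across
cycles (panel SNPs may drift to fixation and then simply carry no signal).

## Metrics

Genetic gain is the standardized TBV difference Δσg = (mean TBVci − mean
TBVc5)/sd(TBVc5) against the first tracked cycle's initial population.
Inbreeding uses the VanRaden method-1 GRM, G = WWᵀ/(2Σp(1−p)) with W
centered at twice the baseline (cycle-five) frequencies; F is the mean
diagonal minus one and ΔF = (Fc − Fc−1)/(1 − Fc−1). Genomic F can pass 1
under extreme drift from the baseline; the per-cycle rate is then recorded
as missing. Replicate-level scenario contrasts use two-sample pooled
t-tests at p < 0.01 (Welch by flag). One extra initial population is
generated after the last cycle purely to record the final gain and
inbreeding point.

## What the generator does and does not emulate

The simulator reproduces the genomic features that drive GS behaviour —
realistic LD decay and heterozygosity for an outcrossing population,
pleiotropy-based genetic correlations, mixed effect-size architectures,
drift and selection-driven inbreeding. It does not model dominance or
epistasis, genotype-by-environment interaction, non-normal errors,
homoeologous exchange between subgenomes, multi-allelic loci, genotyping
error, or selfing. Passing desk-scale tests therefore demonstrates the
internal consistency of the machinery and the direction of scheme
contrasts, not calibrated absolute gains for any real program; desk-scale
inbreeding rates in particular run higher than full-scale ones because the
candidate pools are twenty times smaller.

One desk-scale limit is documented rather than papered over: the contrast
between the 1,000 × 1 and 100 × 10 crossing schemes on the inbreeding rate
is a small effect that the desk replicate variance swamps (the elite-
parent bottleneck induced by the top-pair cap dominates family-size
structure), so it is not statistically detectable at 20 desk replicates,
while the same comparison's gain-neutrality is. The SB-round and
initial-design contrasts are robust at desk scale.

## Numerical and reproducibility choices

All stochastic steps draw from R's RNG — including the C++ meiosis kernel,
which uses the R API — so a single `set.seed()` makes any run
bit-reproducible, and `run_experiment()` derives per-replicate and
per-cell seeds deterministically from one master seed. Within a replicate
the phenotypic warm-up is shared across grid cells, giving paired scenario
comparisons. The Cholesky factorizations reject rank-deficient empirical
covariances with actionable errors; ridge systems solve the primal or dual
form, whichever is smaller; the Gibbs sampler at full-scale settings
(50,000/10,000) is available by argument where the desk default is
2,000/500. Tests and bundled analyses use the desk profile throughout:
base population 300 plants × 3,000 loci run for 2,000 generations,
breeding runs of 2 warm-up plus 4 tracked cycles, 10 replicates for
calibration checks and 20 for directional ones.
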