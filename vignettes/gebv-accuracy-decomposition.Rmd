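---
title: "Decomposing genomic prediction accuracy into relationship and LD components"
author: "gebvcv package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing genomic prediction accuracy into relationship and LD components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genomic estimated breeding values (GEBVs) predict the genetic merit of a
selection candidate from its SNP genotypes and SNP effects estimated in
a phenotyped, genotyped training population.  Two sources of information
feed these predictions: population-wide linkage disequilibrium (LD)
between markers and QTL, which is fairly persistent over generations,
and additive-genetic relationships between the candidate and the
training animals, which decay by half each generation.  A
cross-validation that ignores family structure mixes the two and
overstates the accuracy that will be available for future, less-related
candidates.  `gebvcv` implements a cross-validation design in which the
maximum pedigree relationship between any training bull and any
validation bull — written `a_max` — is controlled, so the decay of
accuracy with relatedness can be measured and the persistent LD
component isolated.

The package targets progeny-testing dairy-cattle data: the phenotype of
a bull is its daughter yield deviation (DYD), a weighted mean of its
daughters' yields corrected for systematic effects, with a reliability
that grows with the daughter count.

## Models

Three predictors are implemented, all with residuals weighted by the
DYD reliability `w_i` (`Var(e_i) = sigma2_e / w_i`):

* **BayesB** (`fitBayesB()`): `y_i = alpha + sum_k x_ik beta_k delta_k
  + e_i`, where `x_ik` counts copies of one SNP allele (0/1/2),
  `delta_k` is a Bernoulli(`pi`) inclusion indicator and `beta_k |
  sigma2_beta_k ~ N(0, sigma2_beta_k)`.  Both variances carry
  scaled-inverse-chi-square priors with 4.2 degrees of freedom.  The
  per-locus variance scale derives from the partition of the additive
  variance over the expected number of included loci,
  `sigma2_beta = sigma2_a / (pi * sum_k 2 p_k (1 - p_k))`.  The sampler
  updates `(delta_k, sigma2_beta_k)` jointly by a Metropolis–Hastings
  step that proposes from the prior and accepts on the likelihood with
  `beta_k` integrated out analytically; included effects, the intercept
  (flat prior) and the residual variance are Gibbs steps.  This
  proposal-from-the-prior scheme needs no tuning constants, and at
  `pi = 1` with a fixed locus variance it collapses to a Gibbs sampler
  for weighted RR-BLUP — the property the oracle tests exploit.
* **G-BLUP** (`fitBlup()` on a genomic relationship matrix):
  `G = sum_k (x_k - 2 p_k 1)(x_k - 2 p_k 1)' / (2 sum_k p_k (1 - p_k))`
  with allele frequencies pooled over training and validation bulls by
  default (`frequency_source` is an argument, since base-population
  frequencies are rarely available in practice).  This centered
  cross-product form is chosen deliberately: it makes G-BLUP exactly
  equivalent to ridge-regression BLUP on the SNP effects, which the
  test suite asserts to 1e-6.
* **P-BLUP** (`fitBlup()` on the numerator relationship matrix `A`,
  built by the tabular recursion with unknown parents as unrelated
  founders).

`fitBlup()` solves the animal model in the phenotype-space GLS form
`V = sigma2_a K_tt + sigma2_e diag(1/w)`, `ghat = sigma2_a K[.,t]
V^{-1} (y - mu)`.  This is algebraically the same solution as the joint
mixed-model equations including unphenotyped validation equations, but
it never inverts `K`, so a rank-deficient `G` needs no ridge (a `ridge`
argument exists for degenerate inputs and reports itself when used).

GEBVs are `ghat_i = sum_k x_ik betahat_k` (`predictGebv()`), the
intercept excluded.

## Cross-validation design

`sampleSplits()` draws replicate training/validation pairs under the
constraints that (i) no training bull has a relationship above `a_max`
with any validation bull, (ii) at most two validation bulls come from
one paternal half-sib family, (iii) sires of training bulls never enter
validation (their accuracy is unrepresentative of future candidates),
and (iv) a bull enters validation at most once across replicates.
Conflicting bulls are excluded from the replicate entirely; the sampler
is a randomized greedy with restarts that keeps the attempt excluding
the fewest bulls.  Exact minimisation is intentionally out of scope —
on toy pedigrees where exhaustive enumeration is feasible, the test
suite bounds the greedy's excess exclusions at 1.5x the optimum.
`downsampleTraining()` halves a training set while protecting all bulls
related to validation at 0.25 or more (fathers, full and half sibs), so
the halving changes SNP-effect precision, not the relative amount of
close-relative information.

## Accuracy estimation and the LD decomposition

The accuracy of a method in a scenario is estimated from the pooled
validation bulls of all replicates, after centering each replicate's
EBVs by their replicate mean:
`rho = cor(ghat, y) / mean(r_gy)`, where `r_gy(n, h2) =
sqrt((n h2 / 4) / (1 + (n - 1) h2 / 4))` is the selection-index
accuracy of a DYD from `n` daughters and `mean(r_gy)` is the arithmetic
mean over the pooled bulls (not a function of the mean daughter count).
`rho` is reported unclipped, with a warning beyond 1, because clipping
would hide estimator noise.

The decomposition regresses GEBV accuracy on the normalised P-BLUP
accuracy across `a_max` scenarios:
`rho_GEBV(a_max) = rho_LD + d * x(a_max) + eps`, with
`x(a_max) = rho_PBLUP(a_max) / rho_PBLUP(0.6)`.  Because P-BLUP uses
pedigree information only, `x` tracks the decay of relationship
information, and the intercept `rho_LD` is the accuracy that remains
when relationships are extrapolated away — the persistent accuracy due
to LD.  The LD component is assumed constant across scenarios, which
holds here because training and validation bulls come from the same
birth cohorts in every scenario.

## The synthetic-data generator

No public data set with this structure exists, so the package simulates
one, and the generator is first-class, tested code:

* `simulatePedigree()` builds a multi-generation pedigree with
  right-skewed paternal half-sib families (`1 + NegBin` sizes;
  dispersion 0.35 reproduces a mean near 6 with rare families of 30-60
  and more), repeated dams for full sibs, and sons of earlier
  generations re-used as sires (father/son chains).
* `simulateFounderHaplotypes()` draws founder haplotypes from a latent
  Gaussian copula whose autocorrelation decays as
  `exp(-0.07 * Ne * d_Mb)`.  The constant 0.07 was calibrated once so
  that `Ne = 50` — the effective size reported for the breed — yields
  an adjacent-SNP mean r2 of about 0.22 at the panel's 0.064 Mb mean
  spacing, the level observed on the 50K bull chip; r2 then decays
  monotonically with distance.  Allele frequencies are uniform on
  (0.05, 0.95), giving a near-flat MAF distribution with mean ~0.27
  after filtering.  The copula reproduces the short-range LD level and
  monotone decay, but its exponential tail underestimates long-range
  LD (real data keeps r2 ~ 0.07 at 1 Mb); none of the implemented
  analyses depend on the long-range tail.
* `geneDrop()` performs Mendelian gene dropping with Poisson crossovers
  at 1e-8 per bp (1 cM per Mb, the usual cattle map density).
* `traitArchitecture()` places QTL among the simulated loci (excluded
  from the marker panel by the experiment driver, so markers act
  through LD and relationships only) and rescales effects so the
  realized additive variance over a reference cohort matches
  `sigma2_a`.  The default experiment uses 100 QTL with reflected
  gamma(0.4) effects — a few major genes plus many small ones, the
  architecture inferred for dairy yield traits.
* `simulatePhenotypes()` generates DYDs as `y_i = g_i + e_i` with the
  noise variance per bull calibrated so `cor(g_i, y_i) = r_gy(n_i,
  h2)` exactly, and sets the weight to the reliability `w_i = r_gy^2`.
  This makes the accuracy estimator exactly consistent in simulation,
  so a simulation oracle can check it against the true breeding
  values.  Daughter counts default to a truncated log-normal (median
  ~120, range 30-5000), spanning the observed range from young test
  bulls to heavily used proven sires; real cohorts have a strong
  birth-year structure in the daughter counts that this does not
  emulate.

What passing tests on these data do **not** show: performance under
selection (mating here is random), multi-breed or admixed LD
structure, long-range LD, X-linked inheritance (the X-masking QC rule
is exercised on constructed fixtures only), genotyping error, or
phasing uncertainty (synthetic haplotypes are known by construction;
`imputeMissing()` exists for file inputs and is deliberately naive).

## Default study conditions and problem sizes

`experimentConfig()` encodes the package's reference experiment, sized
for a desk machine: ~1,100 genotyped bulls over three generations,
~2,170 markers after QC on five 28.2 Mb chromosomes, the `a_max` grid
{0.6, 0.49, 0.249, 0.1249}, 15 replicate pairs per scenario,
validation sets of 20 (12 for the smallest `a_max`, which admits fewer
eligible bulls), and training sizes 700 and 350 — the same ratios as
the motivating full-scale design (2,096/1,048 training bulls,
validation 33/11).  At this scale one full run takes a few minutes of
one CPU core.  MCMC defaults inside the experiment are 2,500 rounds
with 1,000 burn-in; `bayesBConfig()`'s own defaults are the full-scale
50,000/40,000, and the effective-sample-size warning flags chains that
are too short for their data.  Chain-length sensitivity is covered by
the `pi = 1` oracle test, which bounds the sampler's agreement with
the closed-form solution.

## Numerical choices and degenerate inputs

* Strict inequalities in QC ("less than 5% missing", "MAF greater than
  3%") as printed on the source chip filter; MAF is computed after
  X-masking over non-missing calls (the masking rule creates
  missingness, so the order matters; the reverse order is not offered).
* `filterSnps()` reports one reason per SNP, missingness before MAF.
* The tabular `A` recursion sorts by birth year, which the `Pedigree`
  validity guarantees is a topological order; cyclic pedigrees are
  therefore unrepresentable rather than detected late.
* `fitBlup()` reports a condition estimate when the phenotype
  covariance cannot be Cholesky-factorised instead of silently
  regularising.
* Monomorphic SNPs are rejected by `genomicRelationshipMatrix()` (zero
  denominator) and dropped with a warning by `ldR2Profile()`.
* A zero-variance trait architecture is flagged as degenerate, not
  silently propagated.
* All generators and samplers take explicit seeds; the MCMC uses R's
  RNG stream, so `set.seed`-style reproducibility extends into the
  compiled sampler.  Stage seeds in `runExperiment()` are derived by
  hashing the stage name with the master seed, so adding a scenario
  never perturbs the others.

## Known limitations

* The greedy split sampler is heuristic; its optimality gap is bounded
  only on small instances.
* `rho_LD` inherits the sampling error of four accuracy estimates
  through a 4-point regression; with a few hundred pooled validation
  bulls per scenario its Monte-Carlo spread is several hundredths.
  Comparisons between methods are more stable than absolute values
  because they share validation bulls and DYD noise.
* Variance components are inputs, not estimated (no REML step); the
  experiment driver uses the plug-in `sigma2_e = sigma2_a (1 -
  mean(w))`, consistent on average with the DYD noise model.
* Only direct GEBVs are evaluated; blending with pedigree EBVs by
  selection-index weighting is out of scope, as is cosegregation
  modelling and the accuracy of Mendelian sampling terms.
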