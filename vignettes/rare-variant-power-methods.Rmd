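---
title: "Methods: calibrated simulation and permutation-based power for rare-variant tests"
author: "RareVarPower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated simulation and permutation-based power for rare-variant tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RareVarPower)
```

# Overview

RareVarPower is a simulation laboratory for gene-based rare-variant
association testing. It has three layers: a genotype generator calibrated
to printed per-gene summaries of a Sanger-sequenced cohort (n = 1,998,
seven genes), a phenotype simulator implementing six control scenarios and
a systematic effect-by-causal-fraction grid, and seven association tests
whose significance is always assessed by phenotype permutation so that
power comparisons across methods are on an equal footing. This vignette
records the modelling assumptions, the tunable parameters, and the design
decisions taken where the published summaries under-determine the
procedure.

# The genotype generator

## What it emulates

The original genotypes are proprietary, so panels are synthesized to match
the public calibration targets per gene: total and rare (MAF < 1%) variant
counts, the median MAF, the per-variant missing-genotype rate, the coding
length, and the histogram of individuals by number of rare variants
carried. Across genes about 55% of variants are singletons; per-gene
singleton fractions are not printed, so the packaged defaults were chosen
once to be jointly consistent with (i) each gene's median MAF — the median
variant must be a singleton for genes 1, 2, 3 and 5 and a doubleton for
genes 4, 6 and 7, given the rare fractions — and (ii) a pooled singleton
fraction of 279/508 = 54.9%.

The rare-variant allele-frequency spectrum is a truncated neutral-like
power law: singletons are placed in the exact per-gene count, and the
remaining rare minor-allele counts are drawn i.i.d. from
P(AC = k) proportional to 1/k on 2..AC_max, where AC_max is the largest
count still below the 1% MAF threshold (39 at n = 1,998). The drawn
non-singleton counts are then rescaled by a single factor chosen to
minimize the chi-square distance between the *expected* carrier-count
histogram — a Poisson-binomial over variants, since each variant's minor
alleles are placed in carriers sampled without replacement — and the
profile's histogram. This one-dimensional calibration was preferred over
matching the histogram's implied allele total or its implied carrier count
directly, because a linkage-free exchangeable placement model cannot hit
both at once for every gene: the observed cohort is over-dispersed
relative to independent placement for some genes and under-dispersed for
others. Minimizing the histogram distance balances the two and keeps, for
example, the mean number of rare-variant carriers of the largest gene
within a fraction of one cohort standard deviation of the observed tally.

Common variants draw an allele frequency log-uniformly in (0.01, 0.5) and
genotypes under Hardy-Weinberg, redrawing until the realized MAF stays
common, so the rare-variant count of a panel is exact by construction.

## What it does not emulate

There is no linkage disequilibrium (rare variants are not expected to be
in high LD, and the tests studied here do not exploit LD), no population
structure or relatedness, no coalescent genealogy, and no functional
annotation. Passing calibration tests therefore shows that the *marginal*
per-gene summaries are reproduced, not that higher-order haplotype
structure of real sequence data is. The carrier-count histograms are the
one place where between-variant dependence in the real cohort leaks into
the targets; the calibration above absorbs it only on average.

## Missingness and imputation

`applyMissingness()` masks entries i.i.d. at the profile's per-variant
rate (3-11% across genes). `imputeByMAF()` replaces each missing dosage by
an independent Binomial(2, f-hat) draw, with f-hat the allele frequency of
the observed entries of that variant. Sampled genotypes were chosen over
best-guess or expected dosages deliberately: a best-guess rule imputes 0
for every rare variant, making imputation a no-op exactly where it
matters, while a sampled draw propagates the estimated frequency into the
imputed calls. Variants with every entry missing raise an error (frequency
undefined); a variant whose observed frequency is zero is imputed
all-zero, which is the correct degenerate case.

# Phenotype simulation

All scenarios share one backbone: non-carriers of any causal allele draw
N(0, 1); a carrier of at least one *rare* causal allele draws a single
value from N(mu, 0.2^2); a carrier of only common causal alleles draws
N(mu_c, 1.01^2) with mu_c = -0.07 under the fixed-mean model. Effects are
not additive across carried variants, and rare effects take precedence
over common ones. When one individual carries rare causal variants with
conflicting effects (possible in the bidirectional scenarios), the effect
of the carried variant with the smallest MAF wins, ties broken by lowest
variant index — the sources are silent here, and non-additivity forces
some deterministic single pick; rarest-wins is the choice most aligned
with the inverse-frequency logic of the weighting methods.

The fixed magnitudes are -1.64/+1.64 SD for rare effects (the bottom 5% of
the null distribution) with residual SD 0.2, and -0.07 (SD 1.01) for
common effects. Under the inverse-MAF model the effect of causal variant j
is -2.5 * w_min / w_j with w_j = sqrt(n q_j (1 - q_j)) and
q_j = (m_j + 1)/(2n + 2), so the rarest causal variant attains exactly
-2.5 SD.

Causal-set rules: scenario 1 none; scenario 2 all rare variants; scenario
3 exactly 4 rare + 4 common; scenario 4 15% of rare variants, half
deleterious and half protective (odd counts give the extra variant to the
deleterious side); scenario 5 samples with probability proportional to
1/MAF; scenario 6 samples uniformly. Scenario 5's published description is
internally ambiguous — the eligible pool is unrestricted but the count is
anchored to "10% of rare" variants; we resolve it exactly that way
(pool = all variants, count = 10% of the rare pool), and scenario 6
analogously with 10% of all variants. Fractional counts round half-up
deterministically. The grid crosses effects {0.5, 0.75, 1, 1.25, 1.5, 2,
2.5} SD with causal fractions {10, 15, 20, 30}% of rare variants,
optionally with a 50/50 direction mix; with seven genes this is the
196-cell systematic design. The default is 250 phenotype replicates per
(gene, scenario), resampling the causal set each replicate.

Dichotomous traits label the 500 lowest phenotypes cases and the 500
highest controls (extreme quarters of 1,998), ties broken stably by
individual index so label counts are always exact.

`varianceExplained()` reports both Var(E[y|carrier status])/Var(y) and the
unnormalized between-group variance, because the normalization of the
published variance-explained table is not stated; no downstream result
depends on the choice.

# Association tests and permutation

All gene-level tests share one permutation engine. For burden-type
statistics the continuous-trait t statistic is a monotone function of
|centered-score x y| under phenotype permutation (the total sum of squares
of y is permutation-invariant), so the engine permutes cheap inner
products; the reported statistic is still the t value (continuous) or the
case/control mean-score difference (dichotomous). Within one replicate all
methods consume the same permutation stream, which removes between-method
Monte-Carlo noise from power contrasts.

P-values are p = (b + 1)/(B + 1), hence strictly positive. The default cap
is B = 1000; the adaptive rule evaluates, after every batch of 100, a 99%
normal confidence interval for p and stops once it excludes alpha = 0.05 —
the rejection decision is then settled, and only decisions (not exact
p-values) enter power. For exact small-sample work the engine can
enumerate all n! permutations (n <= 9), where p becomes the exact fraction
of orderings, identity included, at least as extreme as the observed one.
Ties between permuted and observed statistics are counted as exceedances,
with a relative tolerance of 1e-9 guarding floating-point equality.

Method-specific notes:

* **T1/T5** sum minor-allele counts (not carrier indicators) below the
  threshold, matching the reference implementation of the collapsing
  tests; MAFs come from the full sample for continuous traits and from
  controls for dichotomous ones (the weighted-sum convention).
* **WE** uses weights 1/w_j as above; with all weights equal it reduces
  exactly to the unweighted test, which is tested.
* **VT** takes candidate thresholds at every distinct observed MAF and
  re-maximizes |z(t)| inside every permutation, so the threshold search is
  fully reflected in the p-value. With one distinct MAF it degenerates to
  the fixed-threshold statistic.
* **WOD** (weighted outlier detection) is a reconstruction: no complete
  public definition of the original outlier-detection statistic exists, so
  this package authors one from its documented behaviour. The behavioural
  constraints are clear: a
  continuous-trait statistic, strong when carriers are pushed into either
  phenotype tail by large effects, weak under small unidirectional shifts,
  and not defined for dichotomous traits. Our construction: each
  individual receives a two-sided tail score
  s_i = -log(2 min(F(y_i), 1 - F(y_i))) from a Gaussian-kernel smoothed
  CDF F of the phenotypes (evaluated on a 512-point grid, clipped at the
  empirical resolution 1/(2n)); the statistic sums s_i over carriers of
  any allele at or below the MAF threshold, and permutation re-draws the
  carrier set. Estimating F from *all* phenotypes — rather than from
  non-carriers only — keeps the per-individual scores fixed under
  permutation, which makes the test exactly exchangeable (and fast); the
  cost is a slight dilution of the reference distribution under strong
  alternatives, a conservative direction. Under the null the scores are
  approximately Exp(1) draws; carriers at ±1.64 with residual SD 0.2 score
  around 2.3, which is what gives the test its bidirectional power, while
  small unidirectional shifts (0.5 SD) actually *lower* the carrier scores
  below the null mean — reproducing the intended weakness. The statistic
  is invariant under y -> -y by construction (mirror symmetry of the
  kernel CDF), and this invariance is tested to floating precision.
* **SKAT** is the variance-component score Q = (y - mu)' G' W^2 G (y - mu)
  over *all* variants, with Beta(MAF; 1, 25) density weights and mu the
  intercept-only fit (mean phenotype, or case fraction). The primary
  p-value is permutation-based for cross-method comparability; a
  Satterthwaite moment-matched scaled chi-square p (matching E[Q] and
  Var[Q] under the null via traces of the centered weighted kernel) is
  reported alongside and agrees with the permutation p on null data.
* **Single-marker scan**: per-variant simple OLS with two-sided t tests
  and a Bonferroni threshold alpha/m; monomorphic variants get p = 1 with
  a warning rather than an error, so panel-level scans never abort.

# Power estimation

`estimatePower()` draws, for every (gene, scenario, replicate), a fresh
causal assignment and phenotype, runs all requested methods, and reports
rejection rates with Monte-Carlo standard errors sqrt(p(1-p)/R), plus
unweighted gene averages. A method erroring on a replicate (e.g. a gene
with no variant below a threshold) counts as a non-rejection and is
surfaced through one summarizing warning per cell — conservative, and the
way untestable genes behave in practice. Everything derives from a single
master seed through per-(gene, scenario, replicate, purpose) substreams,
so partial re-runs reproduce the corresponding slices of a full run and
two runs of the same plan are bit-identical.

`carrierCaseProbability()` is the closed-form companion for the
extreme-sampling design: the case threshold is the case-fraction quantile
of the carrier/non-carrier mixture (found by root-finding to 1e-10), and
the returned value is the carrier CDF there. At effect zero there are no
causal effects, so carriers draw from the same N(0,1) background as
everyone else and the probability equals the case fraction exactly — the
limiting case is handled explicitly rather than through the degenerate
N(0, 0.2^2) carrier distribution, which would not describe any simulated
scenario.

# Problem sizes and reproducibility

The packaged test suite and the acceptance script use the study-scale
design where it matters and reduced designs where only a property is being
checked: null calibration and the scenario-2 positive control run the full
seven genes x 250 replicates (B = 500 and 200, adaptive); the
single-marker ceiling uses 100 replicates per grid cell over effects up to
1.5 SD; generator fidelity averages 200 panel draws per gene; property
suites (exhaustive permutation oracles, quadratic-form identities,
degeneracies, monotonicities) use toys of 5-20 individuals or single
genes with 60-80 replicates, with stochastic comparisons allowed 2x
Monte-Carlo-SE slack. These sizes are the package's chosen defaults for a
single-CPU desk run; all of them scale up by changing plan arguments.

# Known limitations

* WOD is a principled stand-in, not the original statistic; conclusions
  about WOD transfer only at the level of its documented behaviour.
* No covariates anywhere (the simulated phenotypes are covariate-free;
  residualize first if needed), no additive or polygenic architectures,
  no gene-gene interaction, and no population stratification — real
  cohorts violate all four.
* The generator reproduces marginal summaries; haplotype structure,
  mutation-age effects and ancestry-dependent spectra are out of scope.
* Adaptive permutation settles decisions, not exact p-values; reported
  p-values at early stop are coarse (that is intentional — power is a
  decision rate).
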