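---
title: "Models and methods for sow thermotolerance genetic parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for sow thermotolerance genetic parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Heat stress in lactating sows is usually monitored through physiological
indicators: automatically recorded vaginal temperature (a core-body proxy),
skin surface temperatures, respiration rate, panting score, and
slower-changing anatomy such as body condition, hair density and ear size.
Selecting for heat tolerance requires genetic parameters for these
indicators — heritabilities, repeatabilities, genetic correlations — and
those are estimated with genomic mixed models whose inputs come from messy
sensor streams: 5-minute barn climate loggers, 10-minute temperature
monitors, 4x/day manual counts.

`sowtherm` implements that whole chain as testable code: a synthetic-data
generator that emulates the study design, the phenotype-derivation and
filtering rules, genotype quality control and a genomic relationship
matrix, a Gibbs sampler for the variance-component models, model selection
by DIC, and the reporting layer (heritability, repeatability, genetic
correlation, GEBV accuracy). Because the raw commercial data of such
studies cannot be shared, the generator is a first-class module: every
downstream stage is exercised against data with known truth.

## Statistical models

Repeated-record traits are analysed with a repeatability model

$$\mathbf{y} = \mathbf{X}\beta + \mathbf{Z_a a} + \mathbf{Z_{pe} pe} + \mathbf{e},$$

with $\mathbf{a} \sim N(0, \mathbf{G}\sigma^2_a)$,
$\mathbf{pe} \sim N(0, \mathbf{I}\sigma^2_{pe})$,
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$; single-record traits drop the
permanent-environment term. $\mathbf{G}$ is the VanRaden method-1 genomic
relationship matrix computed from post-QC SNP codes centered at observed
allele frequencies, blended with 5% identity so the sampler can invert it.
Derived quantities are

- heritability $h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)$,
- repeatability $r_e = (\sigma^2_a + \sigma^2_{pe}) / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)$,
- genetic correlation $r_g = cov_{12} / \sqrt{\sigma^2_{a1}\sigma^2_{a2}}$,
- per-sow theoretical accuracy
  $\sqrt{1 - \widehat{SD}^2_i / ((1+F_i)\hat\sigma^2_a)}$ with $F_i$ the
  unblended G diagonal minus one and $\widehat{SD}_i$ the posterior SD of
  the sow's sampled additive effect.

All ratio summaries are posterior means of per-draw ratios (with the
posterior SD as the reported spread), not ratios of posterior means; the
two differ and the per-draw convention matches the Bayesian software this
field uses.

## Gibbs sampler

`gibbs_fit()` samples full conditionals in effect blocks: fixed effects
jointly through a Cholesky solve of $X'X$; the additive block in the
eigenbasis of blended G, which makes each iteration O(q^2) (and O(q) in
rotated coordinates) for balanced designs — unbalanced designs fall back to
a per-iteration Cholesky of the animal-block precision; permanent-
environment effects per animal. Variances are drawn from scaled inverse
chi-square conditionals with the flat-prior convention (posterior degrees
of freedom = data df − 2); the bivariate additive covariance matrix from an
inverse-Wishart conditional (flat prior: df = q − 3).

Bivariate fits update each trait's fixed/pe blocks conditional on the other
trait's current residuals, and the two additive blocks jointly per
eigen-index (a 2x2 solve, vectorized) when the record sets are paired and
balanced. Residual covariance across traits is estimated only when the two
traits' records pair one-to-one on (animal, day, time); with disjoint
structures (e.g. a repeated trait against a single-record trait) it is
structurally zero, which is the only coherent choice for unmatched records.
Permanent-environment effects are fitted trait-specific (diagonal pe
covariance) because the generator defines per-trait pe variances with only
a genetic covariance across traits; a full pe covariance would not be
identified any better at the scales analysed here.

Per-draw conditional deviance (the Gaussian likelihood of y given all
effects) is stored; `compute_dic()` uses the Spiegelhalter form
DIC = mean deviance + p_D with p_D = mean deviance − deviance at the
posterior means. This conditional-deviance DIC matches what the reference
animal-breeding software reports, and is comparable only between fits of
the same records.

Chain profiles: the reference profile is 100,000 iterations, 40,000
burn-in, thinning 30; the desk profile (20,000 / 5,000 / 10) is used for
tests, the analysis scripts and the recovery experiments, and at those
problem sizes (300-700 animals, up to ~19,000 records) runs in under a
minute per fit. Convergence can be checked with the package's Raftery-Lewis
implementation (the two-state Markov-chain construction on the indicator of
exceeding the empirical 2.5% quantile; defaults q = 0.025, r = 0.005,
s = 0.95), which agrees with the `coda` reference implementation in tests.

## The synthetic-data generator

The generator emulates the study design rather than pig physiology:

- **Genotypes.** Allele frequencies uniform on a MAF window; unrelated
  animals are Binomial(2, p) draws. Because a commercial sow herd is
  organised in sire families, and because separating $\sigma^2_a$ from
  $\sigma^2_{pe}$ at a few hundred animals hinges on relatedness, the
  recovery experiments use the paternal half-sib option (gene dropping from
  binomially drawn founders) with about 25 daughters per sire — a typical
  AI-boar family size. Deliberately QC-failing SNPs and animals can be
  injected to exercise the QC stage. Missing genotypes are
  missing-completely-at-random.
- **Climate.** One diurnal sinusoid (default: mean 28 degC, amplitude 4
  degC, peak at 16:00) plus white logger noise (SD 0.5 degC), 5-min ticks;
  relative humidity iid normal truncated to (0, 100]. This is the simplest
  structure that reproduces an afternoon heat peak; it has no day-to-day
  weather, no heat waves and no room-cooling events.
- **Phenotypes.** Record = systematic means (intercept, parity, location,
  recorder, time-of-day) + climate slope x (hourly average temperature,
  centered at the daily mean) + additive value + per-animal pe + residual.
  Ordinal scores cut a continuous latent record at fixed thresholds, even
  though the analysis treats scores on the observed scale — realistic score
  distributions with a linear analysis model. Fixed-effect magnitudes are
  not reported in the literature for this design, so defaults are small
  (parity deviations of 0-0.08 trait SD) and exposed as parameters.

What passing recovery tests show: the estimation chain is consistent with
its own generative model at the stated scales. What they cannot show:
robustness to the features real barn data have and the generator does not —
informative missingness (loggers failing in hot rooms), diurnal genetic
variation, non-Gaussian residuals, recorder drift.

## Simulation truths and the desk-scale recovery experiments

True variance components for the recovery experiments are set to the
published posterior means for this trait panel
(`reference_variance_components()`): e.g. all-record vaginal temperature
has additive variance 0.0620 with $h^2 = 0.15$ and $r_e = 0.37$; the noon
single-record temperature $h^2 = 0.29$; ear area $h^2 = 0.40$; caliper and
visual body-condition scores correlate genetically at 0.92; respiration
rate and panting score at 0.87. The experiments simulate 300-700 animals
(desk scale, versus ~1,400-1,600 in the real study), 1,000 SNPs (versus
~49,500 post-QC), fit with the desk Gibbs profile, and compare the
posterior-mean estimate with the truth. Each scenario is measured as the
mean over 2-4 independent simulate-and-fit replicates: the replicate
average estimates the method's expected recovery rather than one draw of
its sampling distribution.

## Numerical choices and edge cases

- Dew point uses the Magnus-Tetens constants a = 17.62, b = 243.12 degC,
  valid on [-45, 60] degC; RH above 100 (sensor artifact) is clamped to
  100, RH <= 0 rejected. At saturation the identity DP = DBT holds exactly.
- Hour assignment is half-open, [H:00, H+1:00); hourly aggregates average
  all surviving logger records in the room-hour.
- The outlier rule is a single pass: mean and SD are computed once on the
  unfiltered trait (iterating would remove different records); filters act
  per trait across the whole dataset. Respiration rate keeps [12, 172] bpm.
- Respiration efficiency uses all available 8:00/16:00 pairs across days,
  dropping incomplete pairs listwise; fewer than 2 pairs or constant RR
  yields a missing value, not an error. Lower values mean more cooling per
  breath; no sign flip is applied.
- G blending (default 5% identity) guarantees a positive-definite system;
  genomic inbreeding uses the unblended diagonal, since blending is a
  numerical device rather than a genetic quantity.
- `genetic_correlation()` clips |r_g| <= 1 only for floating-point noise
  (< 1e-8); accuracy ratios that exceed 1 through Monte-Carlo noise are
  reported as 0 with a flag.
- Zero-variance simulations pass through the whole pipeline: the sampler's
  variance draws stay near zero and reports show h^2 near 0.

## Known limitations

- At desk scale, posterior-mean heritabilities carry a small upward spread
  (right-skewed posteriors under flat variance priors), visible for
  single-record traits with a few hundred animals.
- High genetic correlations are systematically attenuated toward zero at
  desk scale: with 1,000 SNPs and half-sib families, cross-trait additive
  covariance is weakly separable from residual covariance (single records)
  or permanent-environment effects (low-heritability repeated records),
  and the flat inverse-Wishart prior then pulls the bounded parameter
  toward 0. The effect is strongest for the respiration-rate/panting-score
  pair (truths h^2 = 0.06/0.05): its recovered posterior-mean r_g sits
  around 0.75 against a true 0.87. The sampler itself is verified unbiased
  at stronger information in the test suite. Full-scale data (thousands of
  animals, dense SNP panels) do not show this.
- Ordinal traits are analysed on the observed scale; threshold-liability
  models are out of scope, so heritabilities for scores are
  observed-scale quantities.
- Random-regression (reaction-norm) models and fits of more than two
  traits are out of scope.
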