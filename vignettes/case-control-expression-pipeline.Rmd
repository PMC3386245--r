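---
title: "Methods: case/control expression analysis with downstream genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/control expression analysis with downstream genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decohort)
library(dplyr)
```

decohort implements the analysis chain used in post-mortem brain
case/control expression studies — here modelled on a prefrontal-cortex
Parkinson disease design with 27 cases and 26 controls profiled on a
one-color expression array — together with the downstream genetics that
such studies attach to a transcription-factor finding: binding-site
enrichment, a targeted eSNP interaction scan, mediation decomposition, and
summary-statistic meta-analysis. This vignette describes each model, its
assumptions, and the numerical and design choices made where the procedure
left room.

## Probe quality control and normalization

Probes are removed by two rules, applied before any normalization:

1. **Detectable range, per group.** A probe is dropped when its signal
   falls outside the detectable spike-in range in more than 50% of the
   control arrays *and* more than 50% of the case arrays. The detectable
   range itself is not modelled: it arrives as a per-probe-per-sample
   boolean flag (`InDetectableRange`), supplied with the data or
   simulated. Requiring failure in *both* groups keeps probes that are
   expressed in one group only — which are exactly the interesting ones.
2. **Feature flags, overall.** A probe is dropped when any single quality
   flag (`IsWellAboveBG = 0`, `gIsSaturated = 1`, `gIsFeatPopnOL = 1`,
   `gIsFeatNonUnifOL = 1`) takes its failing value in more than 75% of all
   arrays.

Both fractions are strict inequalities and configurable via
`filter_policy()`. Replicated probes surviving the filter are collapsed to
their per-sample median — filtering happens first, on the replicate rows,
so a bad replicate can be removed without dragging down its siblings; the
two operations do not commute and the pipeline fixes this order.

Quantile normalization forces every array to the cross-array mean of order
statistics (limma's implementation with `ties = TRUE`: tied values within
a column receive the mean of the reference values at their tied ranks — a
deterministic, standard tie rule), and log2 is taken *after* normalization,
not before. Array-level outlier exclusion is deliberately out of the main
path: `detect_outlier_arrays()` offers a conservative heuristic (mean
inter-array Spearman distance beyond 3 MADs) but is off by default, since
interactive quality review is not reproducible from code.

## Differential expression

Each probe's log2 expression is modelled by ordinary least squares:

$$y_i = \beta_0 + \beta_{\text{status}}\,\mathbb{1}[\text{case}_i]
  + \gamma_1 \text{RIN}_i + \gamma_2 \text{PMI}_i + \gamma_3 \text{age}_i
  + \varepsilon_i$$

with a two-sided t test on $\beta_{\text{status}}$ and Benjamini–Hochberg
FDR control across probes. Cases are coded 1 so positive coefficients mean
higher expression in disease. The adjustment set is a configurable list;
its default (RIN, PMI, age at death) reflects the usual choice of RIN over
pH when the two are correlated tissue-quality measures — including both
would over-adjust. No empirical-Bayes moderation is applied: at n = 53 the
per-probe residual degrees of freedom are ample, and plain OLS keeps the
estimates interpretable as group differences.

Numerical conventions: a zero-variance response returns
$\beta = 0, p = 1$ rather than `NaN`, keeping the FDR vector total;
rank-deficient designs are an error naming the collinear columns; fold
change is $2^{|\beta|}$ with direction from the sign ($\beta = 0$ reports
"up" by tie convention). The fold-change scale assumes $\beta$ sits on
log2 data; a raw-scale ratio would be a different estimand and is not
silently substituted.

`run_diffexpr()` vectorizes the fit across probes through one QR
decomposition (all probes share the design); tests assert it is
numerically identical to looping `lm()`.

## Gene-set enrichment and direction of change

Enrichment of a significant gene list in a TFBS set is summarized two
ways: *fold enrichment*, the ratio of the fraction of significant genes in
the set to the background fraction, and an uncorrected Pearson chi-square
on the 2×2 membership table with its odds ratio, Bonferroni-adjusted over
the number of sets. A gene counts as significant when any of its probes
is FDR-significant. Continuity correction is off by default — the classic
Yates correction is conservative at these counts and is available behind a
flag.

The direction-of-change test asks whether significant probes in the set
go *up* in cases more often than the remaining significant probes
(excluding the factor's own probes, which would trivially inflate the
association). The cross-study overlap test is the same chi-square applied
to two top-gene lists over their common universe.

## Targeted eSNP scan

For each SNP × probe pair the 2-df model compares

$$y \sim d + \text{status} + d\cdot\text{status} + \text{covariates}
  \quad\text{vs.}\quad y \sim \text{status} + \text{covariates}$$

where $d$ is the dominant-coded genotype (carriers of ≥ 1 minor allele),
testing the genotype main effect and the genotype-by-status interaction
jointly. An F test (2 df) is used rather than the asymptotic chi-square:
at n ≈ 50 the F reference keeps the type-I error calibrated (the suite
verifies 0.05 ± 0.015 over 2000 null simulations); the LRT p-value is
attached for comparison. Stratified case-only and control-only slopes are
reported alongside. With dominant coding, a stratum in which the genotype
is monomorphic makes the interaction inestimable; the fit then falls back
to the 1-df genotype model and reports the stratified estimate as missing.
SNPs are pre-filtered at MAF ≥ 0.1 and missing dosages drop samples
per SNP.

Multiplicity uses the eigenvalue-based effective number of tests: the
smallest number of principal components of the SNP correlation matrix
whose eigenvalues reach 99.5% of the total, computed per LD region and
summed when regions are supplied, on additive dosages by default. The
corrected threshold is $\alpha/m_\text{eff}$ (Bonferroni) or the Šidák
form. Because probe sets are also scanned, the pipeline multiplies
$m_\text{eff}$ by the number of probes tested; both factors are explicit
in the output rather than folded into one opaque number.

## Mediation decomposition

For a hub transcription factor $x$, a candidate mediator $m$ and binary
status $y$, three adjusted regressions are fitted: logistic
$y \sim x$ (total effect $c$), linear $m \sim x$ (path $a$), and logistic
$y \sim m + x$ (paths $b$ and $c'$). Mixing linear and logistic models
requires putting slopes on one scale before multiplying: coefficients are
standardized as $\beta \cdot \text{sd(predictor)}/\text{outcome scale}$,
where the logistic outcome scale is the latent-liability convention
$\sqrt{\operatorname{var}(\hat\eta) + \pi^2/3}$. The scale of step 3 is
shared by $b$ and $c'$ so that the indirect effect
$a^\ast b^\ast$ and the direct effect $c'^\ast$ are commensurable and
"% of total effect mediated" $= \text{indirect}/(\text{direct} +
\text{indirect})$ is well defined. The observed-proportion alternative
scale was considered and rejected as the default because the latent scale
makes the decomposition approximately additive
($c^\ast \approx c'^\ast + a^\ast b^\ast$; the suite checks the residual
non-collapsibility error stays under 10% of the total at n = 2000).

The indirect-effect null is tested with the first-order Sobel statistic
$z = ab/\sqrt{a^2 se_b^2 + b^2 se_a^2}$ — first-order rather than
second-order, matching the statistic's common usage, and conservative when
both paths are null (rejection well below $\alpha$; calibration is exact
when one path is present, which the suite verifies under $a = 0, b \ne 0$).
Standardization cancels in $z$, so the test is invariant to affine
rescaling of $x$ and $m$. No bootstrap intervals and no joint
multiple-mediator model are provided: mediators are tested one at a time,
which is the design this package mirrors.

## Meta-analysis engines

Two engines cover the two summary-statistic situations:

* **Weighted Z** for p-value + direction data:
  $z_i = \Phi^{-1}(1 - p_i/2)\,\text{sign}_i$, combined as
  $\sum w_i z_i/\sqrt{\sum w_i^2}$ with $w_i = \sqrt{n_i}$. With equal
  sample sizes this is exactly unweighted Stouffer.
* **Inverse variance** for beta/SE data, with genomic control: each
  study's SE is inflated by $\sqrt{\lambda}$ when its
  $\lambda = \text{median}(\chi^2_1)/0.4549$ exceeds 1 — never deflated,
  so over-clean studies are not up-weighted. Whether genomic control
  should inflate SEs or deflate test statistics is a known ambiguity in
  tool implementations; SE inflation is adopted and recorded here.

A study contributes nothing to a SNP when its direction symbol is `?`,
which unifies two exclusion routes: the SNP is absent from the study, or
it was imputed with quality Rsq < 0.30 (strict inequality; genotyped
entries are never filtered on Rsq). Direction strings such as `+++?++`
round-trip through `direction_strings()`/`parse_direction()`. p↔z
conversions go through the normal survival function for stability at
extreme z.

## The synthetic cohort generator

`simulate_cohort()` exists so every stage can be exercised, calibrated and
scored against known truth without access to any real cohort. Its defaults
are fixed study conditions, not tuning knobs:

* 27 cases, 26 controls; age ≈ 76 ± 8; RIN ≈ 7.4 ± 0.8 truncated to
  (0, 10]; pH ≈ 6.67; PMI lognormal with a shorter case mean (≈ 6.5 h vs
  ≈ 12 h) — post-mortem interval is the one covariate tied to status, so
  confounding is present but controllable.
* 10,000 probes over 8,000 genes (desk-scale; the platform being emulated
  has ~45,000 probes, but the analyses' behaviour depends on the DE
  fraction and set structure, not the raw probe count), ~1.3% of probes
  differentially expressed at 0.4 log2 units, 32% of genes in the hub
  TFBS set, a DE enrichment odds ratio of 2 for that set, and
  direction-of-change fractions of 0.78 (in set) vs 0.66 (elsewhere).
* One eSNP (MAF 0.15) among 52 SNPs in 13 LD blocks, with genotype effect
  −0.49 and an additional −0.24 in cases, mirroring a case-stronger
  regulatory effect. The target is a TFBS DE probe *outside* the mediator
  set: mediator probes carry an extra unit-scale latent signal that would
  mask a log2-scale genotype effect at n ≈ 50.
* A liability model that makes mediation true by construction: hub latent
  $x \sim N(0,1)$, ten mediators $m_j = a x + \sqrt{1-a^2}\,\epsilon$,
  liability $c' x + b \sum_j m_j$ plus logistic noise; the top 27 samples
  by liability score become cases. Fixing group sizes exactly (rather
  than Bernoulli-drawing status) matches how case/control cohorts are
  assembled and keeps every simulated data set the same size.

Randomness is organized in named substreams (structure, covariates,
liability, genotypes, expression, flags) derived from one master seed, so
enlarging the probe set cannot perturb the genotype draws — fixtures stay
stable as configurations grow.

What the generator does *not* emulate, and what passing tests therefore do
not show: probe sequence effects and hybridization physics, between-array
batch structure, cell-type composition shifts in diseased tissue, and the
strong co-expression among real TFBS gene modules. That last point
matters for interpretation: because the ten simulated mediators split the
indirect path and are conditionally independent given the hub, each one
mediates only a modest share (~10%) individually, whereas real co-expressed
mediator genes can each appear to mediate 25–50% in one-at-a-time analyses.
Parameter-recovery tests for the mediated share therefore use the direct
single-mediator generator `simulate_mediation_cohort()`, whose true share
is $ab/(c' + ab)$ in closed form.

LD genotypes come from a thresholded latent Gaussian factor model; the
within-block parameter r is a latent correlation, and realized genotype
correlations are attenuated (tetrachoric-style) relative to it. This is
intentional: allele-frequency-dependent attenuation is how real dosage
correlations behave.

## Problem sizes used by the shipped checks

Simulation-backed checks run at sizes chosen to make Monte-Carlo error
comfortably smaller than the tolerance being asserted: 2000 null data sets
(n = 50) for the 2-df test's type-I error (±0.015), 1000 for Sobel
calibration (±0.02), 200 data sets of n = 5000 for recovering a 40%
mediated share (±3 points), 2000 assignments for the enrichment odds
ratio (±5%), and a handful of full default cohorts for DE-beta
unbiasedness (bound noise_sd/√n ≈ 0.034). The acceptance script re-runs
the same computations from scratch under a caller-supplied seed.

## Known limitations

* The enrichment chi-square uses plain membership counts; EASE-style
  jackknifed counts used by some annotation servers would give slightly
  more conservative p-values.
* Mediation assumes no unmeasured mediator-outcome confounding and no
  exposure-mediator interaction; neither is testable from these data.
* The 2-df eSNP model treats expression as the outcome in a retrospective
  (status-sampled) design; slopes are interpretable, but stratified
  intercepts are not population quantities.
* Meta-analysis is fixed-effect only; between-study heterogeneity is not
  modelled.
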