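---
title: "Models and methods behind telodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind telodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telodyn)
```

`telodyn` analyses longitudinal telomere-length data from pedigreed animal
colonies. This vignette is the package's own account of the statistical
machinery: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data validation does and does not
establish.

## The measurement model: qPCR T/S ratios

Relative telomere length is quantified as the T/S ratio: the amount of
telomere-repeat signal (T) over single-copy-gene signal (S), each expressed
in ng-equivalents of a common reference DNA. The assay's physical model is
that the quantification cycle Ct is linear in log10 of input template, so a
per-plate, per-target standard curve

Ct = slope · log10(ng) + intercept

is fit by ordinary least squares to a five-level, 3-fold dilution series
(2.22–180 ng, i.e. an 81-fold span), and unknowns are interpolated by
inverting the line. Amplification efficiency is `10^(-1/slope) - 1`; perfect
doubling per cycle corresponds to slope −3.3219 and efficiency 1.

Choices a user can move:

* **Replicate aggregation** (`aggregate_replicates`): reactions run in
  triplicate; a replicate more than 0.5 cycles (default, configurable) from
  the replicate median is discarded, the survivors are averaged, and falling
  below two survivors raises a QC flag. No aggregation rule is canonical in
  the qPCR literature; median-distance screening is common practice and the
  threshold is exposed.
* **Reference normalization** (`compute_ts(reference = )`): published T/S
  values are sometimes re-expressed relative to a designated reference
  sample. Both conventions are supported; the default is the raw
  standard-matched quantity ratio, and a reference sample, when designated,
  is normalized to T/S = 1.
* **Extrapolation flagging** (`quantify(tol = )`): quantities outside the
  calibrated dilution range (±10% by default) are returned but flagged.

Vendor software applies undocumented curve adjustments; `telodyn`
deliberately uses plain least squares, which is what a standard curve
denotes. Upstream fluorescence processing (baselining, thresholding, melt
analysis) is out of scope: input begins at Ct values.

## Kinship

`compute_kinship` implements the classical recursion in topological order:
founders have self-kinship 1/2 and zero mutual kinship; for an individual
with sire f and dam m, φ(i,i) = ½(1 + φ(f,m)) and φ(i,j) = ½(φ(f,j) +
φ(m,j)). Founders are assumed non-inbred and mutually unrelated — the
standard convention when deeper ancestry is unrecorded. An individual with
exactly one recorded parent receives a unique phantom founder as the other
parent, which keeps the recursion total without creating spurious
relatedness. The matrix is stored dense: study cohorts are a few hundred
animals, so sparse machinery would buy nothing.

The additive-genetic covariance of the polygenic model is 2Φ (the numerator
relationship matrix). Tests verify the recursion against two independent
oracles: exhaustive enumeration of all inheritance vectors on small
pedigrees, and Monte-Carlo gene dropping (20,000 drops) on random 30-member
pedigrees.

## The polygenic variance-components model

The phenotype of n related animals is modelled as

y = Xβ + g + e,  g ~ N(0, σ²g · 2Φ),  e ~ N(0, σ²e · I),

where X holds an intercept plus covariates (sex, age, diet, a tested
biomarker, …). Estimation is full maximum likelihood (not REML): 2Φ is
eigendecomposed once, y and X are rotated into the eigenbasis where the
covariance is diagonal, β is profiled by GLS and the total variance
σ²p = σ²g + σ²e analytically, leaving a one-dimensional search over
h² = σ²g/σ²p on [0, 1] (`stats::optimize`, tolerance 1e-8). Standard errors
come from the observed information — a numerical Hessian of the joint
log-likelihood in (β, σ²g, σ²e) — with the h² SE by the delta method.

Assumptions worth stating: multivariate normality of the trait (hence the
i-normalization below), additivity of the genetic effect (no dominance,
epistasis, or shared-household component), and homogeneous environmental
variance. ML rather than REML matches the variance-decomposition approach
this pipeline mirrors; REML would change variance-component SEs slightly and
is a well-known alternative the package does not currently expose.

Numerical corner cases, and how they are resolved:

* **Flat ridge.** When 2Φ = I (all animals unrelated) the likelihood does
  not depend on h²; the fit returns h² = 0 with an `h2_unidentifiable` flag.
  More generally, whenever h² = 0 attains the maximum within numerical
  noise, 0 is returned in preference to an arbitrary interior point.
* **Boundary estimates.** h² estimates at 0 or 1 are returned as-is with an
  `h2_boundary` flag; the h² standard error is NA there (the quadratic
  approximation is meaningless on the boundary).
* **Semi-definite kinship.** Eigenvalues of 2Φ below −1e−8 (relative) abort
  with a covariance error; tiny negative values from floating-point are
  clamped to zero.

### Hypothesis tests

Covariate effects are tested by likelihood-ratio tests against χ²₁, with the
null and full models fit on the identical rows (listwise deletion on the
full covariate set happens first). Heritability is a variance component
tested on the boundary of its parameter space, so the LRT statistic is
referred to the mixture ½χ²₀ + ½χ²₁: p = ½·P(χ²₁ ≥ Λ), and Λ = 0 gives
p = 0.5. Both tests are calibrated by simulation in the test suite (1000
null replicates each): the covariate test's rejection rate at α = 0.05 must
lie in [0.035, 0.065] and the boundary test must not exceed 0.065.

### Association summaries

Biomarker and lesion associations are reported the way epidemiological
tables print them: the predictor joins the polygenic model as a covariate,
R² = β̂²·Var(x)/Var(y) is the proportion of trait variance attributable to
it, r = sign(β̂)·√R², and P comes from the covariate LRT. This definition is
chosen because it makes P(r = 0) identical to P(β = 0) in the model and
forces R² = r² exactly — a consistency the pipeline verifies on every
report. The naive alternative (plain correlation on adjusted data, ignoring
kinship) is deliberately not the primary route, since it ignores the
non-independence the whole model exists to absorb.

## Transforms

* **i-normalization** (`inverse_normal_transform`): values are replaced by
  Φ⁻¹((r − ½)/n) of their midranks. The (r − ½)/n offset is symmetric and
  standard; Blom's (r − 3/8)/(n + ¼) is available as an option. Missing
  values stay missing and do not consume ranks.
* **Residualization** (`residualize`): OLS residuals on intercept + sex +
  age (+ interactions). Zero-variance covariates are dropped; a
  rank-deficient design is an error rather than a silent pseudo-inverse.
* **ΔLTL** (`delta_ltl`): baseline minus follow-up, so telomere *shortening
  is positive*. Two modes record whether inputs were raw i-normalized values
  or sex/age-adjusted residuals; the arithmetic is identical, the mode is
  metadata. For per-cohort analyses the difference is taken on values
  i-normalized within the analysis set.

## The exact permutation median test

`exact_mwu_test` permutes group labels and uses the rank-sum of the first
group (midranks under ties) as statistic — the rank-sum orders samples
identically to the Mann–Whitney U, and being a rank statistic it is robust
to outliers and invariant under monotone transforms. When
choose(na+nb, na) ≤ `max_exact` (default 2×10⁶) the null distribution is
enumerated completely; two-sided p doubles the smaller tail, capped at 1
(the convention most software prints). Larger problems fall back to seeded
Monte Carlo with ≥10⁵ permutations and the add-one correction
(k+1)/(B+1), which keeps the p-value valid and never exactly zero. A
"median test" implemented as a Mood-style dichotomy would be a different
statistic; the rank-sum is used and documented because it is the standard
reading of a Wilcoxon-Mann-Whitney test of medians.

## The synthetic-data generator

The generator exists because colony data of this kind are not publicly
deposited: every downstream stage is validated against simulated studies
with known truth.

**Pedigree.** Discrete non-overlapping generations with random mating: a
limited pool of breeding males per generation (polygyny — each dam is
assigned one sire), Poisson litter weights, geometric growth from 28
founders to a final generation of ~130 over six generations. Only the
kinship structure, not the mating system, enters the likelihood, so the
mating scheme is tuned to one summary: the mean pairwise kinship of a
sampled study cohort, which under the defaults is ≈ 0.15 (10th–90th
percentile roughly 0.12–0.18 across colony realizations) — between half and
full siblings, matching the 0.14–0.17 reported for the real colony.

**Phenotypes.** On the i-normalized scale,
y = μ + β_sex·sex + β_age·(age − mean age) + β_diet·diet + g + e with
σ²g + σ²e = 1, g drawn with covariance σ²g·2Φ through the eigendecomposition
of the relationship matrix. Two time points share g and an animal-level
environmental effect (default within-animal residual correlation 0.6 — a
free choice, as no test–retest correlation is published); the diet effect
applies only at time point 2 in the experimental cohort. Ages are uniform on
[6, 17] years and sex is Bernoulli with 44% females, mirroring the study's
cohort composition; the uniform shape is a free choice. A raw-scale T/S
value is emitted as the monotone transform 0.90·exp(0.10·y), chosen so
cohort medians sit near the published descriptive table (~0.90 on chow,
~0.86 after the challenge); only its ranks matter downstream.

**Secondary traits.** A biomarker or lesion extent with target correlation r
is built as r·z + √(1−r²)·u on the standardized scale, where z is the
standardized anchor (endpoint LTL, or ΔLTL for traits named `*_delta`) and
u is noise orthogonalized against z *in-sample*, so each replicate's
realized correlation is exactly r. The exactness matters: with plain
population-level mixing the expected squared sample correlation at n ≈ 106
is inflated by (1−r²)²/n ≈ 0.008, which would systematically bias the
recovered variance shares by nearly a full percentage point. When a scenario
fixes the fraction of ΔLTL variance explained by age, attrition is
constructed the same way against standardized age and subtracted from the
baseline value.

**What passing recovery tests does and does not show.** Parameter recovery
demonstrates that the estimators are unbiased under the generator's
assumptions — Gaussian traits, exactly additive genetics, uniform ages,
exact target correlations. Real data depart from all of these (skewed raw
T/S distributions, assay batch effects, age structure tied to pedigree
depth, missingness), so recovery validates the *estimators*, not any claim
about a particular dataset.

## Problem sizes and determinism

Simulation sizes used in validation are chosen to match the study design
they emulate: 200 replicates per scenario at the study's cohort sizes
(n = 211 combined, 105/106 per cohort), 1000 replicates for test-size
calibration at n = 120 on a fixed colony, 20,000 gene drops for the kinship
oracle, and 400 replicates for the genetic-covariance convergence check.
Every stochastic component is seeded: identical (scenario, seed) pairs
reproduce identical studies, and two pipeline runs with the same seed write
byte-identical TSV reports.

## Known limitations

* Univariate traits only: no bivariate genetic models, no
  dominance/household components, no genomic (marker-based) relationships.
* ML standard errors rely on an interior optimum; boundary h² estimates get
  flags, not SEs.
* The exact permutation branch materializes the assignment index matrix and
  hands very large enumerations to Monte Carlo even below `max_exact` when
  memory would suffer.
* The qPCR module starts at Ct values; fluorescence-level artefacts must be
  handled upstream.
* Open questions in the mirrored design are resolved by documented choices,
  not asserted as the original study's: per-cohort (not combined) residuals
  for the separate-cohort ΔLTL analyses, tail-doubling for two-sided exact
  p-values, and no multiple-testing adjustment anywhere (the report counts
  its tests instead).
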