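---
title: "Methods: paired and unpaired EWAS in monozygotic twin cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired and unpaired EWAS in monozygotic twin cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models the package implements,
the choices made where the design was genuinely open, the synthetic
cohort generator and its calibration, and what the test suite does and
does not establish about real data.

## Study design

Monozygotic (MZ) co-twins share their genome, so the within-pair
difference of any trait is free of additive genetic confounding and of
shared-environment effects. The pipeline analyses blood methylation
(Illumina 450K-style beta values, assumed already normalized upstream)
against a quantitative cognitive phenotype measured at two waves roughly
ten years apart, in five scans: paired and unpaired versions of the
cross-sectional (follow-up) and longitudinal (change) analyses, plus a
discordance-stratified paired cross-sectional variant.

## Probe quality control

Five filter criteria operate at two levels, in a fixed order:

1. *Measurement level* — a probe x sample value is masked to missing
   when its bead count is below 3, its detection p-value is strictly
   above 0.01, or the measurement had zero signal. The boundary cases
   matter and are tested: detection p = 0.01 is retained, bead count = 2
   fails.
2. *Probe level* — after masking, probes missing in strictly more than
   5% of samples are dropped, then probes on a user-supplied
   cross-reactive list. The missingness rule is only meaningful after
   measurement-level masking, which is why masking runs first.

Whether "zero signal" should be judged per measurement or per probe is
ambiguous; the package takes it as a per-measurement boolean supplied
with the QC metrics, which subsumes the per-probe reading (a zero-signal
probe has all measurements flagged).

Filtering is idempotent and never alters surviving values. Surviving
betas are transformed to M-values, `M = log2(b / (1 - b))`, the
variance-stabilized scale on which all models operate. The logit base is
not dictated by convention alone — base 2 is the standard M-value
definition for this array family. Betas of exactly 0 or 1 would map to
infinity, so betas are clipped into `[eps, 1 - eps]` with `eps = 1e-6`
(configurable); at that epsilon the most extreme attainable M-value is
about ±19.93.

## The cognitive composite

Six test scores (verbal fluency, immediate and delayed recall,
processing speed, attention, working memory) are z-standardized and
summed. Standardization parameters (per-test mean and SD) are estimated
**once**, on a reference wave, and applied to both waves so the two
composites are commeasurable and their difference is a meaningful change
score. Which wave supplied the parameters is not identifiable from the
published description; the package defaults to intake (baseline), which
makes follow-up decline interpretable, and exposes the choice as an
argument. The estimation population is everyone with the component
observed at the reference wave, with no pair weighting — the simplest
defensible reading.

Missing components: with exactly one missing, the five-score sum is
prorated by 6/5; with two or more the composite is unavailable. Both
rules are exact-arithmetic fixtures in the tests.

Cohort-level decline is tested with an intercept-only linear mixed model
with a twin-pair random intercept (lme4, REML) and a Wald t test of the
intercept. Degrees of freedom for that t are approximate; the package
uses `n_individuals - 1`, which is slightly anticonservative when the
pair variance dominates, and the null-calibration test bounds the
practical consequence (empirical size within the binomial interval of
5% at 100 pairs).

## Cell-composition imputation

Measured leukocyte counts for five subtypes enter the association models
directly. When counts are missing for some samples they are imputed by
multivariate partial least squares (PLS, regression mode, via mixOmics):
responses are `log(count + 1)` for the five subtypes; predictors are
every probe observed in all samples plus sex, follow-up age and chip
position (side, row dummies), each centred and unit-scaled with training
statistics. Zero-variance predictors are dropped — they carry no
information and break scaling. Back-transformed predictions
`exp(pred) - 1` are floored at zero (counts are physical quantities).
Whether the original procedure fed betas or M-values into the imputer is
unstated; betas are the default here and the choice is configurable.
The number of latent components defaults to 10, with an optional
cross-validated grid search (`choose_n_components()`).

The exactness contract is tested: when `log(count + 1)` is a noiseless
linear function of three probes and the irrelevant covariates are
constant, a 3-component fit reproduces held-out counts to machine
precision, and pure-noise predictors give held-out R² below 0.1 (no
leakage).

## Paired scan

Within each complete pair, the *minuend* twin is the one with the
lexicographically smaller sample id — an arbitrary but deterministic
orientation, so rebuilding the design from permuted inputs gives
identical results. Per probe,

```
dM_j = a + b dPhi_j + c sex_j + d age_j + e' dCell_j + eps_j
```

is fitted by OLS over pairs j; the reported quantity is `b` (M-value
units per phenotype unit) with a two-sided t test on
`n_pairs - 8` degrees of freedom. Whether the published model carried an
intercept is unstated; one is included because it absorbs any
orientation-dependent mean shift, leaving the phenotype coefficient
invariant to the orientation convention. Sex is coded female = 1, age in
years uncentred; any full-rank coding gives identical phenotype
inference. Cell adjustment uses raw count differences; the log transform
is reserved for imputation, where it is explicit.

The estimator is certified two ways: against the closed-form normal
equations, and against the within-pair fixed-effects (pair-dummy)
regression on individual-level data, which reproduces the paired
coefficient exactly when the difference model's intercept/sex/age terms
are represented as orientation interactions.

The discordant variant ranks pairs by |phenotype difference|
(descending, ties broken by pair id) and keeps the top
`ceiling(fraction * n)` — applied, as in the source design, only to the
cross-sectional analysis by the pipeline driver.

## Unpaired scan

The individual-level model is `y = X beta + u_pair + e` with
`u ~ N(0, s2_pair)`, `e ~ N(0, s2_resid)`. With clusters of size at most
two the marginal covariance is block-diagonal with 2x2
compound-symmetric blocks, so for a candidate variance ratio
`lambda = s2_pair / s2_resid` the model rotates into independent
heteroscedastic observations — pair sums with variance `1 + 2 lambda`,
pair differences with variance 1, singletons with `1 + lambda` (times
`s2_resid`). The restricted likelihood is profiled over the fixed
effects and `s2_resid`, leaving a one-dimensional criterion in `lambda`
maximized by Brent search on the log scale over `[0, 1e6]`, with the
boundary `lambda = 0` always evaluated; at the boundary the fit is
exactly OLS, including the standard errors. Members of incomplete pairs
are included — their random effect integrates out — which is the
unpaired design's main advantage in sample size.

Inference is a Wald t with `n - 8` degrees of freedom; Satterthwaite-type
corrections are out of scope, and at cohort sizes of hundreds the df
choice is immaterial to the reported p-value ranges. The implementation
is verified against lme4 (estimates, SEs, variance components), against
a dense grid on the profiled criterion (agreement to 1e-4 in restricted
log-likelihood), and for calibration: on a 200-pair null cohort with
within-pair methylation ICC 0.5 the empirical 5% rejection rate of both
scans lies in [0.040, 0.060].

## Reporting and enrichment

Fixed unadjusted thresholds follow 450K EWAS convention: p < 1e-5
reported as suggestive, p < 1e-6 genome-wide significant, p < 1e-4 for
cross-analysis overlap and enrichment input; all comparisons strict.
Probe-level results are not BH-corrected (matching the source design);
BH is available with an **explicit family size** because displayed
enrichment tables are typically truncated to sets passing a display
threshold — inferring the family from the list length would silently
mis-correct. The implementation delegates to `stats::p.adjust` and is
property-tested against a brute-force step-up.

Over-representation uses the one-sided hypergeometric upper tail
(`P(X >= O)`), with the gene universe equal to the unique gene symbols
on the (QC-filtered) array annotation, expectation `E = C n / N` and
ratio `R = O / E`. Probe- and gene-level overlaps are reported
separately since two analyses can share a gene through different probes.
Overlap membership requires the threshold in *both* analyses. Minimum
set size after universe intersection defaults to 1.

## Synthetic cohort generator

Per probe p, individual i in pair j:

```
M_pij = mu_p + u_pj + e_pij (+ cell effects + sex/age effects)
u ~ N(0, sigma2_pair),  e ~ N(0, sigma2_indiv)
```

with baselines `mu_p` drawn bimodally (beta modes near 0.1/0.9).
Cognition is generated *downstream of methylation*: a latent ability
with pair-shared and individual parts (intake ICC configurable) plus a
coupling `kappa * sum(M - mu)` over the causal probes. This direction is
deliberate — the fitted models are symmetric association scans, the test
target is association recovery, and no causal claim is implied either
way. Cross-sectional causal probes feed the ability *level* (present at
both waves), so they do not contaminate the change score; longitudinal
causal probes feed the 10-year change only. Test scores are affine
images of the latent composite plus sum-to-zero per-test noise, so the
pipeline's standardize-and-sum composite recovers the latent scale up to
a factor `sqrt(v_z)` known analytically to the generator.

**Calibration.** The configured `effect_size_m_per_unit` is the
paired-scan estimand: the population slope of the within-pair M-value
difference on the standardized composite difference. Given the variance
algebra (including the standardization rescaling, which feeds back into
the achievable slope), the coupling `kappa` solves a scalar equation
with a saturating right-hand side; the generator takes the smallest
solution and raises an error when the target exceeds the achievable
maximum, with guidance on which variances to change. The calibration is
exact by construction and verified by Monte Carlo: across replicates,
causal-probe estimates centre on the configured effect within two
Monte-Carlo standard errors, and null probes centre on zero.

**Power of planted effects.** Detectability is governed by the causal
probes' residual scale. `expected_paired_power()` computes the implied
within-pair correlation and t noncentrality analytically. The
effect-recovery study conditions (243 pairs, 2,000 probes, five planted
cross-sectional effects of 0.03 M-units per composite unit, all five
expected below p < 1e-5) are met with `causal_sigma2_indiv = 0.08`,
chosen from that calculation (per-probe correlation 0.42, noncentrality
7.1, joint recovery probability about 0.97) before any simulation was
run.

**Defaults.** The demo layout is 20 pairs x 500 probes. Cohort-shape
defaults mirror the motivating cohort: 111/243 female pairs, follow-up
age ~ N(65.9, 6.1²) truncated to [55, 79], intake composite SD 3.71,
mean 10-year decline -1.64 latent units, individual change SD 3,
methylation ICC 0.5 at null probes. Methylation variance components for
cognition-coupled probes are not published anywhere; the defaults here
are chosen for test power, not cohort realism. QC failure rates
(0.2% bead, 0.2% detection, 0.05% zero-signal) give realistic sparse
masking; planted high-missingness probes use an 8% failure fraction,
comfortably above the 5% rule. A single root seed drives one documented
draw sequence (R provides no cheap independent substreams); identical
seeds give bit-identical cohorts, which the tests assert.

**What the generator does not emulate:** co-methylation blocks and LD
structure, batch effects beyond chip position, practice effects in the
cognition battery, raw two-channel intensities, and any dependence of
cell counts on cognition. Passing tests therefore certify the
estimators' statistical contracts (exactness, calibration, unbiasedness,
power under the stated conditions), not robustness to every artefact of
real array data.

## Numerical choices

* OLS scans use a shared QR factorization across all complete probes and
  per-probe refits on complete cases where values are missing; aliased
  columns are dropped by pivot, and results are marked unavailable when
  the phenotype column itself is aliased (e.g. a constant phenotype).
* The REML search uses Brent optimization with tolerance 1e-9 on the
  log-ratio scale; ties between the boundary and the interior optimum
  resolve to the boundary.
* P-value ties in reports sort stably by probe id; pair orientation and
  all other orderings are lexicographic.
* The simulation's truncated-normal ages are drawn by clipping, keeping
  the draw count fixed for reproducibility.

## Problem sizes used in the checks

The acceptance layer runs, by choice, at: 30 pairs x 50 probes
(estimator equivalence), 60 pairs x 20 probes (REML grid), 200 pairs x
2,000 probes (null calibration), 50 replicates of 243 pairs x 2,000
probes (effect recovery), and 100 replicates of 100 pairs (decline
test). These sizes give Monte-Carlo error comfortably below the margins
being tested while keeping a full run around a minute.

## Known limitations

* Only probe-level QC is implemented; sample-level QC is assumed done
  upstream (the pipeline consumes already-normalized betas).
* The unpaired model knows only pair structure, not general kinship.
* No genomic-control or robust-variance options; neither appears in the
  source design.
* The discordance fraction applies to the cross-sectional paired
  analysis in the driver; other combinations are possible through the
  lower-level API but are untested territory.
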