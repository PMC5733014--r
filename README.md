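# twinewas

Epigenome-wide association scans (EWAS) of quantitative phenotypes in
**monozygotic (MZ) twin cohorts** profiled on Illumina 450K-style
methylation arrays, built around the study design used to relate blood
DNA methylation to cognitive functioning in middle-aged twins: because MZ
co-twins share their genome and much of their early environment, the
within-pair difference in methylation is free of genetic and
shared-environment confounding, making discordant MZ pairs a powerful
design for epigenetic association.

The package is aimed at statistical geneticists and epigenetics
researchers who want a tested, reproducible implementation of this
pipeline — and a synthetic-cohort generator that makes every stage
verifiable without access to restricted cohort data.

## What it implements

* **Probe QC and M-values** — measurement-level masking (bead count < 3,
  detection p > 0.01, zero signal), probe-level removal (missing in > 5%
  of samples, cross-reactive list), and the base-2 logit (M-value)
  transform `M = log2(beta / (1 - beta))` with configurable clipping.
* **Cognitive composite phenotype** — six test scores are z-standardized
  with parameters estimated once on the intake wave and summed; one
  missing component is prorated by 6/5, two or more make the score
  unavailable. The 10-year change score is follow-up minus intake, and a
  pair random-intercept model tests cohort-level decline.
* **Blood cell composition** — missing leukocyte counts (monocytes,
  lymphocytes, basophils, neutrophils, eosinophils) are imputed by
  multivariate partial least squares with `log(count + 1)` responses and
  all fully observed probes plus sex, age and chip position as
  predictors.
* **Paired scan** — per probe, OLS of the within-pair M-value difference
  on the phenotype difference, adjusted for sex, age and cell-count
  differences:
  `dM_j = a + b * dPhi_j + c * sex_j + d * age_j + e' dCell_j + eps_j`,
  with the phenotype coefficient `b` reported (t test, `n_pairs - 8`
  df). A discordance-stratified variant keeps the 50% of pairs with the
  largest |phenotype difference|.
* **Unpaired scan** — individual-level model with a twin-pair random
  intercept, `y = X beta + u_pair + e`, fitted per probe by REML with
  the variance ratio profiled out (closed-form GLS on the 2x2 pair
  blocks); includes members of incomplete pairs and avoids the deflated
  p-values of naive OLS on clustered data.
* **Reporting** — annotation joins (gene, distance, CGI feature),
  suggestive (p < 1e-5) and genome-wide (p < 1e-6) tables,
  cross-analysis overlap at p < 1e-4, Manhattan-plot tables, and
  Benjamini-Hochberg adjustment with an explicit family size.
* **Enrichment** — hypergeometric over-representation of hit genes
  against GMT gene sets within the array's gene universe, reporting
  C, O, E = C·n/N, R = O/E, raw and BH-adjusted p.
* **Synthetic cohorts** — `simulate_cohort()` generates beta matrices
  with pair-shared and individual variance, cell-composition and sex/age
  probe effects, planted QC failures and cross-reactive probes, two-wave
  cognition coupled to causal probes, and a ground-truth table. The
  coupling is calibrated so the paired-scan estimand equals the
  configured effect size exactly.

## Worked example

```r
library(twinewas)

co <- simulate_cohort(simulation_presets("demo", seed = 7))   # 20 pairs x 500 probes
bundle <- run_full_study(co)
```

which prints the stage log:

```
qc: 500 probes x 40 samples in
qc: 484 probes kept (16 dropped: missingness=6, cross-reactive=10)
phenotype: composite available for 40 (intake) / 40 (followup), change for 40
phenotype: mean 10-year change -0.120 (p = 0.644)
cells: counts complete, imputation skipped
paired: 20 complete pairs (cognition), 0 excluded
scan paired-cognition: 484 probes, 19/20/18 units
...
report paired-cognition: 0 suggestive, 0 significant
```

Reading the log: the planted QC failures (6 high-missingness probes and
10 cross-reactive ones) are removed before any scan; all 40 individuals
have scorable composites; at demo scale (20 pairs) the decline test and
the scans are underpowered, so an honest null-ish log is expected —
`simulation_presets("full_scale")` (243 pairs x 20,000 probes) is the
powered layout. Per-scan result tables live in `bundle$results`
(estimate in M-value units per composite unit, standard error, p,
annotation columns), threshold tables in `bundle$reports`, and
`bundle$overlap` holds probe- and gene-level intersections at p < 1e-4.

A single probe's mixed-model fit is available directly:

```r
f <- fit_probe_lmm(y, X, pair_ids)
print(f)
#> Pair random-intercept fit (REML): n = 200, sigma2_pair = 0.1069,
#> sigma2_resid = 0.09987, ICC = 0.517
```

## Command line

A thin CLI wraps the package functions:

```sh
Rscript inst/cli/twinewas.R simulate --preset demo --seed 1 --out cohort/
Rscript inst/cli/twinewas.R run --cohort cohort/ --out results/ [--gmt sets.gmt]
```

See `vignettes/twin-ewas-methods.Rmd` for the statistical model, the
generator's design and calibration, and known limitations.
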