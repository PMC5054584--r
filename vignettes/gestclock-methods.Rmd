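---
title: "Methods: gestational-age clocks from neonatal methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gestational-age clocks from neonatal methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gestclock)
```

This vignette documents the statistical methods implemented in gestclock,
the assumptions behind them, the numerical choices that make results
deterministic, and the limits of what the synthetic-data tests demonstrate.

## Data model

The package's central currency is the beta-value matrix: probes in rows,
samples in columns, values in [0, 1] (methylated signal over total signal),
with `NA` marking missing measurements. All cross-matrix operations align
by probe and sample *identifier*, never by position, so matrices from
different cohorts cannot be silently misaligned. Gestational age is held in
decimal weeks everywhere; days are converted at ingest only. For blood-spot
samples collected after birth, the effective GA at sampling is the clinical
GA plus `days_to_sampling / 7` — the sampling delay is taken as an integer
number of days, since finer resolution is not meaningful for archived
spots.

## Quality control

Three steps, in a fixed order:

1. **Detection masking.** A measurement whose detection p-value is strictly
   above 0.001 is set to missing. The inequality is strict ("above" the
   threshold), so a cell at exactly 0.001 is retained.
2. **Missingness filters.** Probes with more than 5 % missing cells are
   removed *first*; sample missing fractions are then recomputed on the
   probe-filtered matrix and samples above 5 % are removed. The order
   matters and is deliberate: removing a failing probe can rescue a
   borderline sample. Both thresholds are read as strict inequalities;
   whether a fraction of exactly 5 % should pass is genuinely ambiguous,
   and we chose strict so that the documented rule ("more than 5 %") is
   literal.
3. **Probe intersection.** When several datasets are processed jointly, any
   probe absent from one is dropped from all, so downstream models only see
   probes measured everywhere.

A pre-screening hook accepts an externally produced exclusion list (for
example from sex-discordance checks); the package does not itself predict
sex or adult age.

## Gold-standard BMIQ calibration

Between-array distribution differences are removed by calibrating every
array to a single reference, the *gold standard*: the probe-wise mean beta
across all training samples, pooled over datasets (pooling over samples
rather than averaging dataset-level means was an open choice; the pooled
mean weights each sample equally and is the simpler estimand).

Both the gold standard and each sample are modelled as a three-component
beta mixture representing unmethylated (U), hemimethylated (H) and
methylated (M) states. The EM fit is fully deterministic:

* **Initialisation** by hard thresholds (U: β < 0.25, H: 0.25–0.75,
  M: β > 0.75) with method-of-moments shape starts — no random restarts.
* **Clamping** of input values to [1e-6, 1 − 1e-6], since the beta
  likelihood is undefined at the endpoints.
* **M-step** by damped Newton iterations on the component's weighted
  log-likelihood, expressed through its sufficient statistics (Σw,
  Σw·log x, Σw·log(1−x)) so each inner evaluation is O(1). Step-halving
  accepts only non-decreasing moves, making the whole procedure a
  generalised EM whose observed-data log-likelihood is monotone
  non-decreasing — a property the tests assert on every fit.
* **Convergence** at relative log-likelihood change < 1e-6 within 500
  iterations (the per-sample fits inside `calibrate_to_gold()` default to
  1e-5: the transport map depends only weakly on the last digits of the
  shape parameters, and matrix calibration fits hundreds of mixtures).
  Non-convergence returns the best fit with `converged = FALSE` and a
  warning rather than an error.
* **State labels** are assigned by proximity of each component's mean to
  the canonical anchors 0.1 / 0.5 / 0.9, weighted by mixture weight. For
  well-separated fits this is identical to ordering by component mean; for
  degenerate inputs (for example all values near 0.5) it ensures the
  dominant component is labelled H rather than arbitrarily U or M.

Calibration assigns each value to the state with maximal posterior (ties
broken toward the lower-mean state), then maps U-state values by beta-CDF
quantile matching from the sample's U component to the gold standard's U
component, M-state values likewise, and H-state values by the linear
dilation that carries the sample's U/H and H/M boundaries onto their
transported images. The map is continuous at the boundaries and strictly
rank-preserving within each state; calibrating the gold standard against
itself is the identity. If a sample's mixture cannot be fitted, values pass
through unchanged with a warning — an identity fallback is safer than
failing an entire pipeline run for one array.

The calibration deliberately treats the whole array distribution as one
object and does not model Infinium type-I/type-II probe chemistry; it is a
*between-sample* calibration, not the original within-sample BMIQ.

## Imputation

Remaining holes are filled by probe-wise k-nearest neighbours (default
k = 10). Neighbours are *probes*, matching the canonical formulation in
which a gene/probe is imputed from similar rows. Distances are Euclidean
over jointly observed samples, rescaled by the fraction observed so that
pairs with different overlaps are comparable; candidate neighbours must be
observed at the target sample. Weighting is inverse distance with a 1e-8
guard; distance ties are broken by lexicographic probe id, so the result is
fully deterministic. A probe with no eligible neighbour falls back to its
own observed mean with a warning. The neighbour-weighting details are not
prescribed anywhere authoritative, so the defaults above are documented
here and frozen by an exact-equivalence test against a naive all-pairs
oracle.

## Clock training and prediction

`ga_clock()` fits the elastic net with mixing parameter α = 0.5 (equal
lasso and ridge contributions) and no covariates besides the CpGs. The
penalty λ is selected by tenfold cross-validation: samples are randomly
partitioned (seeded) into ten near-equal folds, each fold's held-out MSE is
computed for every λ on a path of 100 values log-spaced from λ_max (the
smallest λ with an all-zero solution) down to 1e-4·λ_max, and the λ with
minimum mean CV MSE is chosen — the minimum rule, not the one-standard-error
rule. Folds are not stratified by cohort. Predictors are standardized
internally for fitting; coefficients are reported on the original beta
scale. Whether the original clock analyses standardized probes is unknown;
standardization is the common default and makes the penalty
scale-equivariant.

Prediction is the affine form `intercept + Σ coef_j · β_j`. Clock CpGs
absent from a new dataset are filled with the gold-standard mean for that
probe (with a warning naming them); if more than 20 % of the clock CpGs are
missing, prediction errors out as unreliable. Accuracy is summarised by
Pearson r and the median/mean/SD absolute error in weeks.

## GA acceleration and its associations

Acceleration is the residual from OLS of DNAm GA on clinical GA over the
*combined* prediction set (not per cohort; cohort enters downstream models
as a covariate instead). Birthweight associations are linear models of
birthweight (grams) or birthweight percentile on acceleration with race,
cohort and estimated cell proportions as covariates; clinical GA is added
for grams but not for the percentile, which is GA-adjusted by definition.
Cell proportions are simplex-valued, so all-but-one components enter the
design (dropping the first type) to avoid exact collinearity with the
intercept. Insurance status is a logistic regression of the binary label on
acceleration with the same adjustments; complete or quasi-complete
separation is detected from glm's fitted-probability warnings and flagged
(`separated = TRUE`) — no penalized-likelihood refit is attempted, so
flagged estimates should be treated as unstable.

## Cell-composition estimation

Reference profiles are reduced to discriminating probes: per cell type,
probes are ranked by the difference between that type's mean and the mean
of the remaining types, and the top 50 up- and 50 down-methylated probes
per type (configurable) form the union. Proportions solve
min ‖y − Rw‖² subject to w ≥ 0 and Σw ≤ 1. The inequality constraint —
rather than Σw = 1 — leaves room for cell types absent from the reference
panel, as expected in cord blood where nucleated red cells and progenitors
may be incompletely represented. The QP is solved exactly by active-set
enumeration: with at most a handful of cell types, every subset of zeroed
coordinates (with and without the sum constraint active) yields an
equality-constrained candidate, and the feasible candidate with minimal
objective is the global optimum of this convex problem. The default
cord-blood panel has seven types (six white-cell subtypes plus nucleated
red blood cells), granulocyte-dominant.

## EWAS

Per-CpG association with GA is an ordinary least-squares regression of beta
on effective GA, pooled across cohorts with cohort indicator covariates (a
fixed-effects meta-analysis in one design matrix), optionally adding cell
proportions. All probes share one design, so the scan is one QR
decomposition plus probe-wise residual variances. Betas, not M-values, are
the response. No multiple-testing correction is applied by default — the
scan reports nominal p-values and the count below 0.05 — with
Bonferroni/FDR available through `p_adjust`. Probes with numerically zero
residual variance have undefined statistics; they are flagged `degenerate`
and excluded from significance counts. Robustness to cell-composition
adjustment is assessed by correlating the per-probe t statistics of the
adjusted and unadjusted scans.

## CpG-context enrichment

Islands are consumed as BED intervals; shores are the ±1.5 kb flanks of
islands minus island bases, shelves the next ±1.5 kb minus islands and
shores, clipped at the chromosome start. Intervals are held as
`GRanges` (1-based, closed), with BED's 0-based half-open convention
converted exactly at the file boundary. Island context is mutually
exclusive with precedence island > shore > shelf (whether the original
island-context tests used exclusive categories is not documented; the
precedence rule makes the labels well-defined). Enrichment of a predictor's
CpGs against the eligible universe uses Fisher's exact test (two-sided, the
conventional sum over tables with probability at most the observed). The
reported odds ratio is the sample cross-product estimate, with Haldane's
0.5 correction only when a cell is zero; a table with an empty margin
carries no association information and reports OR = 1. Enrichment against
externally defined probe lists (SNP-in-probe, race-associated CpGs) reuses
the same machinery with user-supplied lists.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of neonatal
methylation cohorts so that every stage is testable without downloads:

* **Cell mixtures**: per-sample proportions from a Dirichlet around a
  granulocyte-dominant seven-type cord-blood profile (concentration 40),
  multiplied into simulated purified reference profiles.
* **GA effects**: a configurable number of causal CpGs (default 50 of
  2000) with beta-per-week slopes drawn from ±[0.005, 0.03], centred
  mid-GA-range. Causal probes are placed at intermediate methylation so a
  linear slope survives the (0, 1) bounds — consistent with GA-variable
  CpGs sitting in the dynamic range rather than at the rails.
* **GA**: uniform over 24–44 weeks, the span covered by neonatal cohorts;
  a fraction of samples (default 20 %) are blood spots with integer
  sampling delays of 0–39 days, so the effective-GA correction is
  exercised.
* **Batch structure**: per-cohort, per-probe beta shifts (SD 0.01 by
  default) across 3 cohorts.
* **Noise** is added on the logit scale (SD 0.3 by default) and
  back-transformed, which keeps values in (0, 1) and reproduces the
  heteroskedasticity of beta values (variance shrinking near 0 and 1).
* **Detection failures** planted at rate 0.005, with failed cells given
  background-level beta noise and detection p-values above the masking
  threshold.

What it does *not* emulate: Infinium type-I/type-II chemistry, probe
cross-reactivity, SNP artefacts, chip-position effects, or realistic
genomic autocorrelation. Tests passing on this generator therefore
demonstrate algorithmic correctness and statistical calibration, not
robustness to every artefact of real arrays.

## Problem sizes and determinism

The default study conditions used by the test suite and the acceptance
script are 2000 probes × 450 samples (300 training / 150 testing) for the
end-to-end clock run, 10,000 draws for mixture-weight recovery, 2000 null
probes for EWAS calibration, and 200 replicates for association-model
calibration — sizes at which the statistical targets are stable across
seeds while a full run stays comfortably desk-scale. Every source of
randomness flows from an explicit seed argument; package functions restore
the caller's RNG state. Reruns with the same seed reproduce outputs
byte-for-byte, including the pipeline's `summary.json`.

## Known limitations

* The clock is linear in beta; nonlinear or transformed-age clocks are out
  of scope.
* The calibration assumes three-state beta-mixture structure; arrays with
  strongly bimodal or degenerate distributions fall back to identity with
  a warning.
* Reference-based deconvolution is only as good as the supplied profiles;
  the bundled profiles are synthetic and real panels must be provided by
  the user.
* Raw intensity processing (IDAT parsing, background/dye-bias correction)
  is not implemented; the package starts from beta values.
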