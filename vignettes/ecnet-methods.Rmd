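---
title: "Methods: centrality mapping, permutation inference and symptom-mixture regression in ecnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centrality mapping, permutation inference and symptom-mixture regression in ecnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ecnet` implements a complete analysis path for a case–control resting-state
fMRI study summarized at the level of a 111-region Harvard-Oxford-style
parcellation: per-subject eigenvector centrality (EC) over the ROI
correlation network, permutation inference on group differences with
family-wise error (FWE) control, exposure-by-diagnosis moderation models,
and weighted quantile sum (WQS) regression of a four-scale symptom mixture
on hub centrality. This vignette records the statistical model behind each
stage, the tunable parameters and their defaults, the numerical choices, and
what the synthetic-data tests do and do not establish.

## The parcellation registry

All tables are indexed against a fixed registry of 111 regions: 48 cortical
regions per hemisphere, 7 subcortical regions per hemisphere (thalamus,
caudate, putamen, pallidum, hippocampus, amygdala, accumbens) and the
brainstem. Indices are 0-based internally; printed tables use 1-based ROI
numbers. The registry is a plain TSV and can be swapped for any alternative
111-region enumeration that satisfies the same 48/48/7/7/1 arithmetic; the
loader enforces those counts so downstream code can rely on them.

## Time-series preparation

Preprocessing assumes spatially preprocessed, denoised data summarized as
ROI × time matrices (ROI means over voxels; `extract_roi_timeseries()` does
this reduction for in-memory 4D arrays plus an integer label volume). Two
temporal steps follow:

1. **Pre-whitening.** Each ROI series is regressed on an intercept and the
   six motion parameters; the lag-1 autoregressive coefficient φ is
   estimated on those residuals by ordinary least squares (not bias-corrected
   Yule–Walker — the plain two-step GLM choice), and the *raw* series is
   filtered as `y[t] − φ·y[t−1]`. The first time point is dropped rather
   than back-cast, so a 396-volume series becomes 395; predictable lengths
   were preferred over a one-sample gain. Estimates with |φ| ≥ 1 are clipped
   to ±0.99 with a warning; constant series get φ = 0 and a degeneracy flag.
2. **Confound regression.** The whitened series are residualized on an
   intercept, the six motion parameters, and the white-matter and CSF
   signals. Residuals are exactly orthogonal to every confound (checked to
   1e-10 in tests). Collinear confound columns are dropped with a logged
   condition number. No global signal regression, band-pass filtering or
   scrubbing is performed.

The open design question — whether the second step should re-estimate φ
after confound removal and iterate — is resolved by following the two-step
description literally: whiten once, then remove confounds.

## Eigenvector centrality

The network for one subject is the ROI × ROI Pearson correlation matrix
shifted by +1, giving entries in [0, 2] and a diagonal of 2. The shift makes
the matrix elementwise positive, so by Perron–Frobenius the leading
eigenvector is real, simple and strictly positive. Because eigenvectors are
invariant to positive rescaling, this convention and the `(1 + r)/2` variant
used by fast-ECM implementations give identical centralities (a test
asserts this); keeping the raw self-correlation + shift on the diagonal
moves the eigenvalue, not the ranking.

EC is computed by power iteration from the uniform vector `1/√n`,
renormalizing each iterate and declaring convergence when the
successive-iterate sup-norm change falls below 1e-12 — a bound on the
reported quantity itself, rather than on eigenvalue drift. The returned
vector has unit Euclidean norm and positive sign. Agreement with a dense
symmetric eigensolver is enforced to 1e-9 over hundreds of random fixtures.
ECM is computed at ROI level (the series are ROI means), not voxel level.

## Hubs of differential connectivity

Group differences in EC are tested per ROI with the linear model
`EC ~ intercept + group + covariates` (covariates: current depression,
psychotropic and opioid use), recording the group t statistic. Inference is
by permutation with max-statistic (Westfall–Young) FWE control across all
111 ROIs: each permutation's maximum statistic forms the null, and each
ROI's corrected p is `(1 + #{max ≥ observed}) / (n_perm + 1)`, so p can
never be 0 and never falls below `1/(n_perm + 1)`. Covariates are respected
inside the permutation scheme via Freedman–Lane: EC is residualized on the
nuisance design, residual rows are permuted jointly across ROIs, the fitted
nuisance part is added back, and the full model is refit. The default
direction is one-sided control > case, with a two-sided option; 1000
permutations and α = 0.05 are the defaults. Permutations are drawn without
enforcing uniqueness, and the seed is recorded in the result and in the
output sidecar.

## Exposure moderation

For each hub, `EC ~ months + psychotropic + opioid + MDD + diagnosis +
months×diagnosis` is fit by Gaussian-identity least squares (the outcome is
continuous and an R² is reported, which fixes the "GLM" reading). Subjects
missing the exposure duration are dropped list-wise and counted. The
within-case simple slope is the sum of the months and interaction
coefficients, with its standard error from the coefficient covariance.
Interaction p-values across hubs are adjusted by Benjamini–Hochberg step-up
— chosen because applying BH to the published eight-outcome table's raw p
column reproduces its corrected column to the printed three decimals in
seven of eight rows (the eighth differs by 0.001, consistent with rounding
of the raw value). Note that BH step-up is *not* idempotent — re-adjusting
adjusted values inflates them again — so the tests assert order
preservation and monotonicity instead.

## Weighted quantile sum regression

Within cases only, the four symptom subscales (re-experiencing, avoidance,
hyperarousal, negative thoughts) are quartile-ranked (0–3; boundary ties go
to the lower quartile) and combined into an index `Σᵢ wᵢ·qᵢⱼ` with
non-negative weights summing to one. Estimation is two-step:

1. Over `n_boot` bootstrap resamples (default 5000), weights are chosen to
   maximize the signed covariate-adjusted association between index and
   outcome. The simplex constraint is handled by a softmax
   reparameterization optimized by Nelder–Mead with five starts (equal
   weights plus four random) at tolerance 1e-8. Failed resamples are
   dropped and counted; more than 50% failing is an error.
2. Weights are aggregated as the mean over resamples whose index |t|
   exceeds 2 (a gWQS-style signal-weighted mean; plain mean by flag; if no
   resample qualifies the mean over all is used with a warning), and the
   resulting index is tested on the full sample in
   `outcome ~ index + covariates`.

The association direction must be declared (default negative, a deficit
hypothesis) so the sign is a modeling decision, not the result of sign
fishing. No train/validation split is used: at n ≈ 45 a split is
infeasible, and none is described for the design this mirrors. The known
cost of the no-split design is mild anti-conservatism under the null —
weights are trained on the same sample they are tested on — which the
acceptance test observes as a modest excess of small p-values (the null
p distribution still passes a KS uniformity check at the 1% level).
Bilateral hub pairs can be averaged into a single outcome column before
fitting, reducing nine hubs to eight outcomes; BH correction is applied
across outcomes.

## Symptom subscale scoring

Item responses are scored 1–3 and summed: 10 re-experiencing items (range
10–30), 14 avoidance (14–42), 10 hyperarousal (10–30), 8 negative thoughts
(8–24). The printed ranges and the worked all-1/all-3 examples force the
1–3 item scale even though interview severity is sometimes described on a
1–5 scale; the summation the ranges arithmetically require is what is
implemented. There is no imputation and no reverse scoring.

## The synthetic cohort: a stated world

`generate_cohort()` emulates the study design end to end: 45 cases and 51
controls, 111 ROIs, 396 volumes at TR = 1.5 s, exposure months on 0–10
(zero-inflated uniform, 10 subjects missing at random), depression only
among cases, item-level symptom responses whose group means track the
published descriptives. Each subject's series follows a five-factor model:
ROI loadings around 1 with 5% per-subject jitter, white factor series,
AR(1) noise (φ = 0.3), and small motion/WM/CSF leakage for the
preprocessing stages to remove. Planted effects act multiplicatively on
hub ROI loadings:

* a case-group deficit of `hub_effect` (default 0.30) at the nine hub ROIs;
* a further within-case reduction of `interaction_slope` (default
  0.03/month) times months on site at the two interaction ROIs;
* a within-case reduction of `symptom_beta` (default −0.15) per unit of the
  planted quartiled symptom index (planted weights 0.65/0.15/0.10/0.10).

Loading-scale effects must be large because the +1 adjacency shift damps
the EC response: a 30% loading deficit moves hub EC by only ~1.5% of its
mean (about 1.2 between-subject SDs). The three defaults were calibrated
once, on pilot grids run before the acceptance tests were written, to the
stated targets — joint nine-hub detection power ≈ 0.8 at 1000 permutations,
interaction sign recovery ≥ 90%, weight recovery within 0.15 — and then
frozen.

What a green test establishes: the pipeline recovers planted structure of
the kind the analysis assumes, at the stated sample sizes, and controls
FWE under an exchangeable null. What it does not establish: behavior under
realistic violations — spatial autocorrelation, motion spikes, scanner
drift, heavy-tailed noise, subject-level network topology differences —
none of which the generator simulates, nor of course any real cohort's
empirical findings, which depend on data this package does not ship.

## Reproducibility and numerical conventions

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. The pipeline fans a single global seed out to per-stage seeds by
a fixed affine counter scheme (modulo 2³¹ − 1) so stages can be rerun
independently; each output table has a JSON sidecar or manifest entry
sufficient to reproduce it. Monte-Carlo p-values use +1 smoothing.
Degenerate inputs fail loudly: constant ROI series abort adjacency
construction naming the ROI, constant exposure aborts moderation, and
constant covariates are dropped with warnings rather than silently
absorbed.

## Known limitations

* NIfTI file IO is not provided (no reader in the dependency footprint);
  4D data must arrive as arrays or as ROI × time tables.
* The moderation stage fits independent per-hub models; no joint
  multivariate model or robust/mixed-effects variants.
* WQS uses a single fixed quartile count (4) and the no-split design
  discussed above; repeated-holdout variants are out of scope.
* The permutation test assumes exchangeable subjects under the null;
  family structure or site effects would need a restricted permutation
  scheme the package does not implement.
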