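# ecnet

Eigenvector-centrality analysis of parcellated resting-state fMRI cohorts.

`ecnet` is for researchers who have a case–control resting-state fMRI study
summarized over an atlas parcellation (here, a 111-region
Harvard-Oxford-style registry: 48 cortical regions per hemisphere, 7
subcortical per hemisphere, brainstem) and want to go from raw ROI × time
series to group-level inference with one reproducible toolchain:

1. **Preparation** — two-step pre-whitening (regress out the 6 motion
   parameters, estimate AR(1) per ROI on the residuals, filter the raw
   series as `y[t] − φ·y[t−1]`), then confound regression against motion,
   white-matter and CSF signals.
2. **Eigenvector centrality (ECM)** — per subject, the ROI network is the
   Pearson correlation matrix shifted by +1 (entries in [0, 2]); the
   centrality vector **v** is the leading eigenvector, `A v = λ₁ v`,
   computed by power iteration to a 1e-12 sup-norm tolerance, unit-norm and
   positive by Perron–Frobenius.
3. **Hubs of differential connectivity** — per ROI, the group contrast in
   `EC ~ group + covariates` is tested with a max-statistic permutation
   null (family-wise error controlled across all 111 ROIs,
   `p = (1 + #{max ≥ t_obs}) / (n_perm + 1)`), with nuisance covariates
   handled by the Freedman–Lane scheme.
4. **Exposure moderation** — per hub,
   `EC ~ months + covariates + diagnosis + months×diagnosis` by least
   squares, Benjamini–Hochberg adjustment across hubs, and within-case
   simple slopes.
5. **Symptom-mixture regression (WQS)** — within cases, a weighted
   quantile sum index `WQS_j = Σᵢ wᵢ qᵢⱼ` over four quartile-ranked symptom
   subscales, with non-negative sum-to-one weights estimated over bootstrap
   resamples and the index tested in `EC ~ WQS + covariates`.

A synthetic cohort generator (`generate_cohort()`) produces a full study —
ROI time series with AR(1) noise and confound leakage, phenotypes, item-level
symptom responses — with planted hub deficits, an exposure-by-diagnosis
interaction, and a planted symptom-index effect, so the entire pipeline is
testable end to end without any imaging data.

## Worked example

A scaled-down synthetic run (96 subjects, 111 ROIs, 120 volumes, 199
permutations, 100 bootstraps — the full-scale demo uses 396 volumes, 1000
permutations and 5000 bootstraps):

```r
library(ecnet)
man <- run_demo("demo-out", seed = 1, scale = "small")
#> [simulate] n_subjects=96 n_roi=111 seed=7920
#> [descriptives] n_variables=8
#> [preprocess] n_subjects=96 n_timepoints=119
#> [centrality] n_subjects=96 n_roi=111
#> [hubs] n_hubs=4 n_perm=199
#> [moderation] n_hubs=4 n_obs=86
#> [wqs] n_outcomes=4 n_boot=100

read.delim("demo-out/hubs.tsv")
#>   roi                                     region hemisphere abbreviation statistic p_fwe
#> 1  62 Inferior Temporal Gyrus, anterior division      right          ITG  4.510409 0.005
#> 2 102                                   Amygdala       left         AMYG  4.402729 0.005
#> 3  66                   Superior Parietal Lobule      right          SPL  3.920261 0.010
#> 4  82   Parahippocampal Gyrus, anterior division      right          PHG  3.544186 0.020
```

The hub table lists the regions whose centrality is significantly lower in
cases than controls after FWE correction and covariate adjustment (`roi` is
1-based; `p_fwe` is floored at `1/(n_perm+1)`). At this reduced series
length the test finds four of the nine planted hubs; the full-length demo
recovers all nine. Downstream, `moderation.tsv` holds the per-hub
interaction models (86 of 96 subjects have exposure months) and `wqs.tsv`
the symptom-mixture fits per hub outcome, e.g.

```r
read.delim("demo-out/wqs.tsv")[, c("outcome", "beta", "se", "p", "p_corrected")]
#>     outcome      beta       se        p p_corrected
#> 1 roi_13_61 -0.001154 0.000262 7.57e-05    0.000303
#> 2    roi_65 -0.000897 0.000631 1.63e-01    0.162532
#> 3    roi_81 -0.001429 0.000549 1.28e-02    0.017133
#> 4   roi_101 -0.001872 0.000604 3.53e-03    0.007069
```

where `beta` is the change in centrality per unit of the weighted symptom
index (negative: higher symptom burden, lower centrality), `roi_13_61` is
the averaged bilateral pair, and `p_corrected` is BH across outcomes. A
weights vector summing to one accompanies each fit
(`fit_wqs()$weights`) and gives each subscale's contribution.

A command-line front end ships in `inst/exec/ecnet`
(`simulate`, `demo`, `run`, stage subcommands, `report`).

## Documentation

The methods vignette (`vignettes/ecnet-methods.Rmd`) documents the models,
defaults, numerical conventions, what the synthetic generator does and does
not emulate, and known limitations.
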