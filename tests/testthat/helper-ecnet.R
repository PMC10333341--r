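# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default run stays fast.

# A reduced cohort: full group sizes but short series, cheap enough for
# repeated use. Planted effects keep package defaults unless overridden.
small_cohort <- function(seed = 1L, ...) {
  generate_cohort(cohort_config(n_volumes = 80L, seed = seed, ...))
}

# Preprocess a cohort and return its centrality table.
cohort_ec <- function(cohort, preprocess = TRUE) {
  cleaned <- lapply(cohort$timeseries, function(s) {
    if (preprocess) {
      pw <- prewhiten_ar1(s$data, s$motion)
      remove_confounds(pw$cleaned, s$motion, s$wm, s$csf)
    } else s$data
  })
  ec_table(cleaned, cohort$phenotype)
}

nuisance_covariates <- function(cohort, ids = NULL) {
  ph <- cohort$phenotype
  if (!is.null(ids)) ph <- ph[match(ids, ph$subject_id), , drop = FALSE]
  ph[, c("mdd", "psychotropic", "opioid")]
}

# Random positive-definite-ish shifted-correlation adjacency on n ROIs,
# built from a random time-series fixture so it goes through the same
# construction path the package uses.
random_adjacency <- function(n, t_len = 50L) {
  build_adjacency(matrix(stats::rnorm(n * t_len), n, t_len))
}
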