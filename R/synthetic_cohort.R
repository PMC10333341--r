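# ---- Synthetic cohort generator --------------------------------------------
# A stated world with the statistical structure the analysis assumes:
# low-rank factor time series per subject, planted centrality deficits at
# hub ROIs in the case group, an exposure-by-diagnosis interaction on hub
# loadings, and a symptom mixture whose planted weighted index drives hub
# loadings within cases. AR(1) noise plus motion/WM/CSF confound leakage
# give the preprocessing stages something real to remove.

#' Configuration for the synthetic cohort
#'
#' Defaults encode the study design the package is built around: 45 cases
#' vs 51 controls, 111 ROIs, 396 usable volumes at TR = 1.5 s, exposure
#' months on 0-10 with 10 missing, and nine planted hub ROIs.
#'
#' @param n_ptsd,n_control Group sizes.
#' @param n_roi Number of ROIs.
#' @param n_volumes Usable time points per subject.
#' @param tr_seconds Repetition time (metadata only).
#' @param hub_rois 0-based ROI indices with a planted centrality deficit in
#'   the case group.
#' @param hub_effect Fractional reduction of hub factor loadings in cases
#'   (0 = null world).
#' @param interaction_rois 0-based ROI indices (subset of the hubs by
#'   default) where exposure months further reduce loadings within cases.
#' @param interaction_slope Fractional loading reduction per month on site,
#'   cases only.
#' @param months_range Exposure duration range in months.
#' @param prob_zero_months Probability of exactly zero months (the exposure
#'   distribution is zero-inflated uniform).
#' @param n_missing_months Subjects with missing exposure (MCAR).
#' @param symptom_weights Planted mixture weights for (re-experiencing,
#'   avoidance, hyperarousal, negative thoughts); non-negative, sum 1.
#' @param symptom_beta Fractional hub-loading change per unit of the planted
#'   quartiled symptom index, within cases; negative means more severe
#'   symptoms lower hub centrality.
#' @param ar_coefficient AR(1) coefficient of the additive noise.
#' @param n_factors Number of latent network factors.
#' @param loading_jitter SD of the per-subject multiplicative loading noise;
#'   sets the between-subject centrality spread.
#' @param noise_sd Marginal SD of the AR(1) noise (factor loadings are ~1).
#' @param seed Integer seed; same seed, bit-identical cohort.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_ptsd = 45L, n_control = 51L, n_roi = 111L,
                          n_volumes = 396L, tr_seconds = 1.5,
                          hub_rois = default_hub_rois(), hub_effect = 0.30,
                          interaction_rois = c(81L, 101L),
                          interaction_slope = 0.03,
                          months_range = c(0, 10), prob_zero_months = 0.3,
                          n_missing_months = 10L,
                          symptom_weights = c(0.65, 0.15, 0.10, 0.10),
                          symptom_beta = -0.15, ar_coefficient = 0.3,
                          n_factors = 5L, loading_jitter = 0.05,
                          noise_sd = 1, seed = 1L) {
  cfg <- list(n_ptsd = as.integer(n_ptsd), n_control = as.integer(n_control),
              n_roi = as.integer(n_roi), n_volumes = as.integer(n_volumes),
              tr_seconds = tr_seconds, hub_rois = as.integer(hub_rois),
              hub_effect = hub_effect,
              interaction_rois = as.integer(interaction_rois),
              interaction_slope = interaction_slope,
              months_range = months_range,
              prob_zero_months = prob_zero_months,
              n_missing_months = as.integer(n_missing_months),
              symptom_weights = symptom_weights,
              symptom_beta = symptom_beta, ar_coefficient = ar_coefficient,
              n_factors = as.integer(n_factors),
              loading_jitter = loading_jitter, noise_sd = noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (n_ptsd < 1L || n_control < 1L || n_roi < 2L || n_volumes < 12L)
      stop("counts must be positive (and n_volumes > 11)")
    if (any(hub_rois < 0L | hub_rois >= n_roi))
      stop("hub ROI index out of range 0..", n_roi - 1L)
    if (any(interaction_rois < 0L | interaction_rois >= n_roi))
      stop("interaction ROI index out of range 0..", n_roi - 1L)
    if (hub_effect < 0 || hub_effect >= 1) stop("hub_effect must be in [0,1)")
    if (length(symptom_weights) != 4L || any(symptom_weights < 0) ||
        abs(sum(symptom_weights) - 1) > 1e-9)
      stop("symptom_weights must be 4 non-negative values summing to 1")
    if (abs(ar_coefficient) >= 1) stop("|ar_coefficient| must be < 1")
    if (n_missing_months < 0L || n_missing_months > n_ptsd + n_control)
      stop("n_missing_months out of range")
  })
  class(cfg) <- "cohort_config"
  cfg
}

# AR(1) series with unit-free marginal sd
ar1_series <- function(n, phi, sd_marginal = 1) {
  innov_sd <- sd_marginal * sqrt(1 - phi^2)
  as.numeric(stats::arima.sim(list(ar = phi), n = n, sd = innov_sd))
}

# Latent severity -> ordinal 1..3 items via Binomial(2, plogis(z))
scale_items <- function(n_items, z) 1L + stats::rbinom(n_items, 2L, stats::plogis(z))

subscale_defs <- function() {
  data.frame(scale = c("reexperiencing", "avoidance", "hyperarousal",
                       "negative_thoughts"),
             prefix = c("re", "av", "hy", "nt"),
             n_items = c(10L, 14L, 10L, 8L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Produces per-subject ROI x time matrices with confound series, a
#' phenotype table, and item-level symptom responses, with the planted
#' effects described in [cohort_config()]. Deterministic given
#' `config$seed`; the caller's RNG state is restored on exit.
#'
#' @param config A [cohort_config()].
#' @return List with elements `timeseries` (named list; each entry has
#'   `subject_id`, `data` (ROI x T), `motion` (6 x T), `wm`, `csf`),
#'   `phenotype` (data frame), `items` (item-level responses), `truth`
#'   (planted quantities: base loadings, per-subject hub multipliers,
#'   planted symptom index), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_ptsd + config$n_control
  ids <- sprintf("S%03d", seq_len(n))
  ptsd <- c(rep(1L, config$n_ptsd), rep(0L, config$n_control))

  # --- phenotype -------------------------------------------------------
  months <- ifelse(stats::runif(n) < config$prob_zero_months, 0,
                   stats::runif(n, config$months_range[1],
                                config$months_range[2]))
  months <- round(months, 2)
  if (config$n_missing_months > 0L)
    months[sample.int(n, config$n_missing_months)] <- NA_real_
  mdd <- ifelse(ptsd == 1L, stats::rbinom(n, 1L, 0.40), 0L)
  psychotropic <- stats::rbinom(n, 1L, ifelse(ptsd == 1L, 0.40, 0.08))
  opioid <- stats::rbinom(n, 1L, 0.04)

  # --- symptom items ---------------------------------------------------
  defs <- subscale_defs()
  mu_case <- c(0.71, 0.71, 0.85, -0.06)
  mu_ctrl <- c(-2.08, -2.41, -2.11, -2.65)
  shared <- stats::rnorm(n, 0, 0.4)
  items <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  scores <- matrix(0L, n, 4L, dimnames = list(NULL, defs$scale))
  for (k in seq_len(4L)) {
    mu <- ifelse(ptsd == 1L, mu_case[k], mu_ctrl[k])
    z <- mu + shared + stats::rnorm(n, 0, 0.7)
    item_mat <- t(vapply(z, function(zz) scale_items(defs$n_items[k], zz),
                         integer(defs$n_items[k])))
    colnames(item_mat) <- sprintf("%s%02d", defs$prefix[k],
                                  seq_len(defs$n_items[k]))
    items <- cbind(items, as.data.frame(item_mat))
    scores[, k] <- rowSums(item_mat)
  }

  # planted quartiled symptom index, cases only, centered at 1.5
  index <- rep(NA_real_, n)
  case_idx <- which(ptsd == 1L)
  if (length(case_idx) >= 8L) {   # quartiling needs a minimal sample
    q <- vapply(seq_len(4L),
                function(k) quartile_rank(scores[case_idx, k]),
                numeric(length(case_idx)))
    index[case_idx] <- drop(q %*% config$symptom_weights)
  }

  phenotype <- data.frame(subject_id = ids, ptsd = ptsd,
                          months_on_site = months, mdd = mdd,
                          psychotropic = psychotropic, opioid = opioid,
                          scores, stringsAsFactors = FALSE)

  # --- base network loadings ------------------------------------------
  k <- config$n_factors
  primary <- (seq_len(config$n_roi) - 1L) %% k + 1L
  L0 <- matrix(stats::runif(config$n_roi * k, 0, 0.25), config$n_roi, k)
  L0[cbind(seq_len(config$n_roi), primary)] <- stats::runif(config$n_roi, 0.8, 1.2)

  # per-subject hub multiplier (planted truth, for tests)
  mult <- matrix(1, n, config$n_roi)
  hub_cols <- config$hub_rois + 1L
  int_cols <- config$interaction_rois + 1L
  for (s in case_idx) {
    mult[s, hub_cols] <- mult[s, hub_cols] * (1 - config$hub_effect)
    if (!is.na(index[s]))
      mult[s, hub_cols] <- mult[s, hub_cols] *
        (1 + config$symptom_beta * (index[s] - 1.5))
    m_s <- months[s]
    if (!is.na(m_s))
      mult[s, int_cols] <- mult[s, int_cols] *
        (1 - config$interaction_slope * m_s)
  }

  # --- time series -----------------------------------------------------
  Tn <- config$n_volumes
  timeseries <- vector("list", n)
  names(timeseries) <- ids
  for (s in seq_len(n)) {
    Ls <- L0 * (1 + matrix(stats::rnorm(config$n_roi * k, 0,
                                        config$loading_jitter),
                           config$n_roi, k))
    Ls <- Ls * mult[s, ]
    FF <- matrix(stats::rnorm(k * Tn), k, Tn)
    noise <- matrix(0, config$n_roi, Tn)
    innov_sd <- config$noise_sd * sqrt(1 - config$ar_coefficient^2)
    e <- matrix(stats::rnorm(config$n_roi * Tn, 0, innov_sd),
                config$n_roi, Tn)
    noise[, 1L] <- e[, 1L] / sqrt(1 - config$ar_coefficient^2)
    for (t in 2:Tn)
      noise[, t] <- config$ar_coefficient * noise[, t - 1L] + e[, t]
    motion <- t(vapply(seq_len(6L), function(i) ar1_series(Tn, 0.9),
                       numeric(Tn)))
    wm <- ar1_series(Tn, 0.5)
    csf <- ar1_series(Tn, 0.5)
    gamma_mot <- stats::rnorm(config$n_roi * 6L, 0, 0.08)
    leak <- matrix(gamma_mot, config$n_roi, 6L) %*% motion +
      outer(stats::rnorm(config$n_roi, 0, 0.25), wm) +
      outer(stats::rnorm(config$n_roi, 0, 0.25), csf)
    X <- Ls %*% FF + leak + noise
    rownames(X) <- paste0("roi_", seq_len(config$n_roi) - 1L)
    timeseries[[s]] <- structure(
      list(subject_id = ids[s], data = X, motion = motion, wm = wm,
           csf = csf),
      class = "subject_timeseries")
  }

  list(timeseries = timeseries, phenotype = phenotype, items = items,
       truth = list(base_loadings = L0, hub_multiplier = mult,
                    symptom_index = index),
       config = config)
}

#' Group descriptives with Welch t and chi-squared tests
#'
#' One row per phenotype variable: group means and SDs (continuous) or
#' counts and percentages (binary), with a Welch two-sample t-test or a
#' chi-squared test p-value. Variables constant in both groups are flagged
#' `degenerate` and left untested.
#'
#' @param phenotypes Phenotype data frame with a binary `ptsd` column.
#' @param variables Columns to summarize; defaults to every column except
#'   `subject_id` and `ptsd`.
#' @return Data frame with columns `variable`, `type`, `case_summary`,
#'   `control_summary`, `statistic`, `p`, `degenerate`.
#' @export
cohort_report <- function(phenotypes,
                          variables = setdiff(names(phenotypes),
                                              c("subject_id", "ptsd"))) {
  g <- as.logical(phenotypes$ptsd)
  if (sum(g) < 2L || sum(!g) < 2L)
    stop("need at least 2 subjects per group")
  one <- function(v) {
    x <- phenotypes[[v]]
    case <- x[g]; ctrl <- x[!g]
    binary <- all(stats::na.omit(x) %in% c(0, 1))
    if (binary) {
      summ <- function(z) sprintf("%d (%.0f%%)", sum(z == 1, na.rm = TRUE),
                                  100 * mean(z == 1, na.rm = TRUE))
      degenerate <- length(unique(stats::na.omit(x))) < 2L
      if (degenerate) {
        stat <- NA_real_; p <- NA_real_
      } else {
        tab <- table(factor(x, levels = c(0, 1)), factor(g))
        ct <- suppressWarnings(stats::chisq.test(tab))
        stat <- unname(ct$statistic); p <- ct$p.value
      }
      data.frame(variable = v, type = "binary", case_summary = summ(case),
                 control_summary = summ(ctrl), statistic = stat, p = p,
                 degenerate = degenerate, stringsAsFactors = FALSE)
    } else {
      summ <- function(z) sprintf("%.2f ± %.2f", mean(z, na.rm = TRUE),
                                  stats::sd(z, na.rm = TRUE))
      degenerate <- stats::sd(x, na.rm = TRUE) == 0 ||
        is.na(stats::sd(x, na.rm = TRUE))
      if (degenerate) {
        stat <- NA_real_; p <- NA_real_
      } else {
        tt <- stats::t.test(case, ctrl)   # Welch by default
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      data.frame(variable = v, type = "continuous", case_summary = summ(case),
                 control_summary = summ(ctrl), statistic = stat, p = p,
                 degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, lapply(variables, one))
}

#' Write a generated cohort to disk
#'
#' Per-subject time-series and confound TSVs, a phenotype CSV, an item-level
#' CSV, and a JSON manifest recording paths, seed and a config digest.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, showWarnings = FALSE)
  paths <- list()
  for (s in cohort$timeseries) {
    p <- file.path(ts_dir, paste0(s$subject_id, "_roi.tsv"))
    utils::write.table(t(s$data), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    conf <- cbind(t(s$motion), wm = s$wm, csf = s$csf)
    colnames(conf)[1:6] <- paste0("motion_", 1:6)
    pc <- file.path(ts_dir, paste0(s$subject_id, "_confounds.tsv"))
    utils::write.table(conf, pc, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[s$subject_id]] <- list(timeseries = p, confounds = pc)
  }
  ph_path <- file.path(dir, "phenotype.csv")
  utils::write.csv(cohort$phenotype, ph_path, row.names = FALSE)
  it_path <- file.path(dir, "items.csv")
  utils::write.csv(cohort$items, it_path, row.names = FALSE)
  manifest <- list(seed = cohort$config$seed,
                   n_subjects = length(cohort$timeseries),
                   n_roi = cohort$config$n_roi,
                   n_volumes = cohort$config$n_volumes,
                   config = unclass(cohort$config),
                   phenotype = ph_path, items = it_path, subjects = paths)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}
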