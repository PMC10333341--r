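# ---- End-to-end pipeline orchestration -------------------------------------

#' Pipeline run configuration
#'
#' Defaults follow the analysis settings the package is built around:
#' 1000 permutations, alpha 0.05, 5000 WQS bootstraps, one-sided
#' control > case hub test, negative-direction WQS, BH multiplicity.
#' A single global seed fans out to per-stage seeds through a fixed
#' counter scheme so stages can be rerun independently yet reproducibly.
#'
#' @param out_dir Output directory.
#' @param cohort A [cohort_config()] for the `simulate` stage (ignored when
#'   `timeseries` and `phenotype` are supplied).
#' @param timeseries,phenotype Optional pre-existing inputs: a named list
#'   of `subject_timeseries` and a phenotype data frame.
#' @param registry_path Registry TSV (default: bundled).
#' @param n_perm,alpha,n_boot Analysis settings.
#' @param hub_direction,wqs_direction Directional choices.
#' @param bilateral_pairs List of 0-based (left, right) index pairs to
#'   average before the WQS stage.
#' @param seed Global seed.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_config(),
                            timeseries = NULL, phenotype = NULL,
                            registry_path = default_registry_path(),
                            n_perm = 1000L, alpha = 0.05, n_boot = 5000L,
                            hub_direction = "control_gt_case",
                            wqs_direction = "negative",
                            bilateral_pairs = list(c(13L, 61L)),
                            seed = 1L) {
  structure(list(out_dir = out_dir, cohort = cohort,
                 timeseries = timeseries, phenotype = phenotype,
                 registry_path = registry_path,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 n_boot = as.integer(n_boot),
                 hub_direction = hub_direction,
                 wqs_direction = wqs_direction,
                 bilateral_pairs = bilateral_pairs,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_seed <- function(seed, counter)
  as.integer((as.numeric(seed) + 7919 * as.numeric(counter)) %% 2147483647)

#' Run the full pipeline
#'
#' Stages: simulate (unless inputs are supplied) -> preprocess (pre-whiten
#' + confound removal) -> centrality -> permutation hub test -> moderation
#' -> WQS, writing the shaped tables and a JSON manifest with seeds and
#' per-stage row counts.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_line <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- load_registry(config$registry_path)
  manifest <- list(seed = config$seed, stages = list())
  stamp <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    log_line("[%s] %s", stage, paste(names(list(...)),
                                     unlist(list(...)), sep = "=",
                                     collapse = " "))
  }

  # simulate ------------------------------------------------------------
  if (is.null(config$timeseries)) {
    cc <- config$cohort
    cc$seed <- stage_seed(config$seed, 1L)
    cohort <- generate_cohort(cc)
    ts <- cohort$timeseries
    ph <- cohort$phenotype
    stamp("simulate", n_subjects = length(ts), n_roi = cc$n_roi,
          seed = cc$seed)
  } else {
    ts <- config$timeseries
    ph <- config$phenotype
    if (is.null(ph)) stop("phenotype table required with external time series")
    stamp("ingest", n_subjects = length(ts))
  }

  # descriptives ---------------------------------------------------------
  desc <- cohort_report(ph)
  utils::write.csv(desc, file.path(config$out_dir, "cohort_descriptives.csv"),
                   row.names = FALSE)
  stamp("descriptives", n_variables = nrow(desc))

  # preprocess -----------------------------------------------------------
  cleaned <- lapply(ts, function(s) {
    pw <- prewhiten_ar1(s$data, s$motion)
    remove_confounds(pw$cleaned, s$motion, s$wm, s$csf)
  })
  stamp("preprocess", n_subjects = length(cleaned),
        n_timepoints = ncol(cleaned[[1L]]))

  # centrality -----------------------------------------------------------
  ec <- ec_table(cleaned, ph)
  write_ec_table(ec, file.path(config$out_dir, "ec_table.csv"))
  stamp("centrality", n_subjects = nrow(ec), n_roi = ncol(ec_matrix(ec)))

  # hub test -------------------------------------------------------------
  covars <- ph[match(ec$subject_id, ph$subject_id),
               c("mdd", "psychotropic", "opioid")]
  hub_res <- permutation_hub_test(ec, covariates = covars,
                                  n_perm = config$n_perm,
                                  alpha = config$alpha,
                                  direction = config$hub_direction,
                                  seed = stage_seed(config$seed, 2L))
  hub_tab <- hub_report(hub_res, registry)
  utils::write.table(hub_tab, file.path(config$out_dir, "hubs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = hub_res$seed, n_perm = hub_res$n_perm,
                            direction = hub_res$direction,
                            alpha = hub_res$alpha),
                       file.path(config$out_dir, "hubs_meta.json"),
                       auto_unbox = TRUE)
  stamp("hubs", n_hubs = length(hub_res$hubs), n_perm = config$n_perm)

  # moderation -----------------------------------------------------------
  hub_idx <- if (length(hub_res$hubs)) hub_res$hubs else default_hub_rois()
  fits <- fit_moderation(ec, ph, hub_idx)
  mod_tab <- moderation_report(fits, registry)
  utils::write.table(mod_tab, file.path(config$out_dir, "moderation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stamp("moderation", n_hubs = length(fits), n_obs = fits[[1L]]$n_obs)

  # WQS ------------------------------------------------------------------
  ec_w <- average_bilateral(ec, config$bilateral_pairs)
  case <- ec_w$group == "case"
  ph_case <- ph[match(ec_w$subject_id[case], ph$subject_id), ]
  scales <- ph_case[, c("reexperiencing", "avoidance", "hyperarousal",
                        "negative_thoughts")]
  roi_cols <- grep("^roi_", names(ec_w), value = TRUE)
  outcome_cols <- roi_cols[vapply(strsplit(sub("^roi_", "", roi_cols), "_"),
                                  function(p) any(as.integer(p) %in% hub_idx),
                                  logical(1))]
  wqs_rows <- lapply(outcome_cols, function(cl) {
    f <- fit_wqs(ec_w[[cl]][case], scales,
                 covariates = ph_case[, c("mdd", "psychotropic", "opioid")],
                 n_boot = config$n_boot, direction = config$wqs_direction,
                 seed = stage_seed(config$seed, 3L))
    data.frame(outcome = cl, beta = f$beta, se = f$se, p = f$p,
               w_reexperiencing = f$weights[1], w_avoidance = f$weights[2],
               w_hyperarousal = f$weights[3],
               w_negative_thoughts = f$weights[4],
               stringsAsFactors = FALSE)
  })
  wqs_tab <- do.call(rbind, wqs_rows)
  wqs_tab$p_corrected <- adjust_pvalues_bh(wqs_tab$p)
  utils::write.table(wqs_tab, file.path(config$out_dir, "wqs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stamp("wqs", n_outcomes = nrow(wqs_tab), n_boot = config$n_boot)

  manifest$elapsed_seconds <- as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs"))
  manifest$n_subjects <- nrow(ec)
  manifest$n_roi <- ncol(ec_matrix(ec))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run a self-contained synthetic demo
#'
#' Generates the default synthetic cohort (optionally scaled down) and runs
#' every pipeline stage into `out_dir`.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param scale `"full"` uses the default 96-subject, 396-volume cohort
#'   with 1000 permutations and 5000 bootstraps; `"small"` shrinks volumes,
#'   permutations and bootstraps for a quick smoke run.
#' @return Invisibly, the run manifest.
#' @export
run_demo <- function(out_dir, seed = 1L, scale = c("full", "small")) {
  scale <- match.arg(scale)
  if (scale == "small") {
    cc <- cohort_config(n_volumes = 120L, seed = seed)
    cfg <- pipeline_config(out_dir, cohort = cc, n_perm = 199L,
                           n_boot = 100L, seed = seed)
  } else {
    cfg <- pipeline_config(out_dir, cohort = cohort_config(seed = seed),
                           seed = seed)
  }
  run_pipeline(cfg)
}
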