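test_that("default config describes the study-sized cohort", {
  cc <- cohort_config()
  expect_equal(cc$n_ptsd + cc$n_control, 96L)
  expect_equal(cc$n_roi, 111L)
  expect_equal(cc$n_volumes, 396L)
  expect_equal(cc$tr_seconds, 1.5)
  expect_equal(sum(cc$symptom_weights), 1)
  expect_error(cohort_config(hub_rois = 111L), "out of range")
  expect_error(cohort_config(hub_effect = 1.2), "hub_effect")
  expect_error(cohort_config(symptom_weights = c(0.5, 0.5, 0.1, -0.1)),
               "symptom_weights")
})

test_that("generated cohort honours shapes, ranges and group structure", {
  coh <- small_cohort(seed = 81)
  expect_length(coh$timeseries, 96L)
  s1 <- coh$timeseries[[1L]]
  expect_equal(dim(s1$data), c(111L, 80L))
  expect_equal(dim(s1$motion), c(6L, 80L))
  expect_false(anyNA(s1$data))
  ph <- coh$phenotype
  expect_equal(sum(ph$ptsd), 45L)
  expect_equal(sum(!ph$ptsd), 51L)
  expect_equal(sum(is.na(ph$months_on_site)), 10L)
  expect_true(all(ph$months_on_site >= 0 & ph$months_on_site <= 10,
                  na.rm = TRUE))
  # MDD restricted to the case group
  expect_true(all(ph$mdd[ph$ptsd == 0] == 0))
  # subscale ranges
  expect_true(all(ph$reexperiencing >= 10 & ph$reexperiencing <= 30))
  expect_true(all(ph$avoidance >= 14 & ph$avoidance <= 42))
  expect_true(all(ph$hyperarousal >= 10 & ph$hyperarousal <= 30))
  expect_true(all(ph$negative_thoughts >= 8 & ph$negative_thoughts <= 24))
  # planted index exists exactly for cases
  expect_equal(!is.na(coh$truth$symptom_index), ph$ptsd == 1)
})

test_that("same seed reproduces the cohort bit-identically, null world is flat", {
  a <- generate_cohort(cohort_config(n_ptsd = 5L, n_control = 5L,
                                     n_volumes = 24L,
                                     n_missing_months = 2L, seed = 9L))
  b <- generate_cohort(cohort_config(n_ptsd = 5L, n_control = 5L,
                                     n_volumes = 24L,
                                     n_missing_months = 2L, seed = 9L))
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$timeseries[[3L]]$data, b$timeseries[[3L]]$data)
  expect_identical(a$items, b$items)

  nullw <- generate_cohort(cohort_config(n_ptsd = 5L, n_control = 5L,
                                         n_volumes = 24L, hub_effect = 0,
                                         interaction_slope = 0,
                                         symptom_beta = 0, seed = 9L))
  expect_true(all(nullw$truth$hub_multiplier == 1))
})

test_that("group centrality deficit at planted hubs grows with hub_effect", {
  mean_hub_gap <- function(he) {
    coh <- generate_cohort(cohort_config(n_volumes = 80L, hub_effect = he,
                                         interaction_slope = 0,
                                         symptom_beta = 0, seed = 83L))
    ec <- cohort_ec(coh, preprocess = FALSE)
    gm <- attr(ec, "group_means")
    mean(gm["control", default_hub_rois() + 1L] -
           gm["case", default_hub_rois() + 1L])
  }
  gaps <- vapply(c(0, 0.15, 0.30), mean_hub_gap, numeric(1))
  expect_lt(abs(gaps[1L]), 5e-4)        # null world: no systematic gap
  expect_gt(gaps[2L], gaps[1L])
  expect_gt(gaps[3L], gaps[2L])         # monotone in the planted effect
})

test_that("cohort_report mirrors the descriptives layout with Welch/chi-squared", {
  coh <- small_cohort(seed = 84)
  rep <- cohort_report(coh$phenotype)
  expect_true(all(c("months_on_site", "mdd", "avoidance") %in% rep$variable))
  expect_equal(rep$type[rep$variable == "mdd"], "binary")
  expect_equal(rep$type[rep$variable == "avoidance"], "continuous")
  # planted separation on symptom scales is overwhelming
  expect_lt(rep$p[rep$variable == "avoidance"], 1e-10)

  # degenerate flag for a constant variable
  ph <- coh$phenotype
  ph$site <- 1
  rep2 <- cohort_report(ph, variables = "site")
  expect_true(rep2$degenerate)
  expect_true(is.na(rep2$p))

  expect_error(cohort_report(data.frame(subject_id = "a", ptsd = 1,
                                        x = 1)), "2 subjects")
})

test_that("a 2-SD planted mean shift is detected at high power", {
  # Welch t at n = 45/51, d = 2: power essentially 1; check p < 0.001
  set.seed(85)
  reps <- replicate(20, {
    ph <- data.frame(subject_id = sprintf("S%02d", 1:96),
                     ptsd = c(rep(1, 45), rep(0, 51)),
                     x = c(rnorm(45, 2), rnorm(51, 0)))
    cohort_report(ph, variables = "x")$p
  })
  expect_true(all(reps < 1e-3))
})

test_that("cohort writes to disk with a manifest", {
  coh <- generate_cohort(cohort_config(n_ptsd = 3L, n_control = 3L,
                                       n_volumes = 20L,
                                       n_missing_months = 0L, seed = 86L))
  d <- withr::local_tempdir()
  mf <- write_cohort(coh, d)
  expect_true(file.exists(mf))
  man <- jsonlite::read_json(mf)
  expect_equal(man$n_subjects, 6L)
  expect_equal(man$seed, 86L)
  ts <- utils::read.delim(man$subjects$S001$timeseries)
  expect_equal(dim(ts), c(20L, 111L))   # time x ROI on disk
  ph <- utils::read.csv(man$phenotype)
  expect_equal(ph$subject_id, coh$phenotype$subject_id)
})
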