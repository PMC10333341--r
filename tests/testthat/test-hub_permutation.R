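# Build a small EC-like table directly; the hub test only needs
# exchangeable rows, so a Gaussian stand-in exercises it faithfully.
fake_ec <- function(n_case, n_ctrl, n_roi, shift_rois = integer(0),
                    shift = 0, seed = 1) {
  set.seed(seed)
  n <- n_case + n_ctrl
  m <- matrix(rnorm(n * n_roi), n, n_roi)
  grp <- c(rep("case", n_case), rep("control", n_ctrl))
  m[grp == "case", shift_rois] <- m[grp == "case", shift_rois] - shift
  colnames(m) <- paste0("roi_", seq_len(n_roi) - 1L)
  df <- data.frame(subject_id = sprintf("S%03d", 1:n), group = grp, m)
  class(df) <- c("ec_table", "data.frame")
  df
}

test_that("planted shifts are detected and p-values respect the Monte Carlo floor", {
  ec <- fake_ec(20, 20, 15, shift_rois = c(3, 9), shift = 2, seed = 51)
  res <- permutation_hub_test(ec, n_perm = 499, seed = 5)
  expect_setequal(res$hubs, c(2L, 8L))       # 0-based
  expect_true(all(res$fwe_p >= 1 / (res$n_perm + 1)))
  expect_true(all(res$fwe_p <= 1))
  expect_s3_class(res, "hub_test_result")
})

test_that("two-sided p-values are invariant to which group is the case", {
  ec <- fake_ec(12, 14, 10, shift_rois = 2, shift = 1.5, seed = 52)
  g <- as.integer(ec$group == "case")
  r1 <- permutation_hub_test(ec, group = g, n_perm = 300,
                             direction = "two_sided", seed = 9)
  r2 <- permutation_hub_test(ec, group = 1L - g, n_perm = 300,
                             direction = "two_sided", seed = 9)
  expect_equal(r1$fwe_p, r2$fwe_p)
  expect_equal(r1$statistic, r2$statistic)
})

test_that("degenerate inputs error or warn as specified", {
  ec <- fake_ec(10, 10, 5, seed = 53)
  expect_error(permutation_hub_test(ec, group = rep(1L, 20), n_perm = 100),
               "two groups")
  expect_warning(permutation_hub_test(ec, n_perm = 99, seed = 1),
                 "coarse null")
  covs <- data.frame(mdd = rbinom(20, 1, 0.5), opioid = rep(0, 20))
  expect_warning(res <- permutation_hub_test(ec, covariates = covs,
                                             n_perm = 120, seed = 2),
                 "constant covariate")
  expect_length(res$fwe_p, 5L)
})

test_that("Freedman-Lane and naive permutation agree when covariates are orthogonal", {
  # With covariates orthogonal to both group and outcome, the max-stat null
  # should coincide in distribution with the unadjusted test.
  set.seed(54)
  ec <- fake_ec(25, 25, 12, seed = 54)
  covs <- data.frame(c1 = rep(c(-1, 1), 25))   # balanced, orthogonal-ish
  null_fl <- permutation_hub_test(ec, covariates = covs, n_perm = 400,
                                  seed = 3)$max_null
  null_naive <- permutation_hub_test(ec, n_perm = 400, seed = 30)$max_null
  ks <- suppressWarnings(ks.test(null_fl, null_naive))
  expect_gt(ks$p.value, 0.01)
})

test_that("hub_report shapes output against the registry", {
  reg <- load_registry()
  ec <- fake_ec(20, 20, 111, shift_rois = default_hub_rois() + 1L,
                shift = 1.6, seed = 55)
  res <- permutation_hub_test(ec, n_perm = 300, seed = 7)
  tab <- hub_report(res, reg)
  expect_named(tab, c("roi", "region", "hemisphere", "abbreviation",
                      "statistic", "p_fwe"))
  expect_true(all(diff(tab$p_fwe) >= 0))        # sorted by p
  expect_true(all(tab$roi >= 1 & tab$roi <= 111))  # 1-based in print

  empty <- res; empty$hubs <- integer(0)
  expect_equal(nrow(hub_report(empty, reg)), 0L)

  short <- fake_ec(6, 6, 10, seed = 1)
  res10 <- permutation_hub_test(short, n_perm = 150, seed = 1)
  expect_error(hub_report(res10, reg), "111 regions")
})
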