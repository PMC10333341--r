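test_that("quartile ranks match hand-computed quartiles of 1..8", {
  expect_equal(quartile_rank(1:8), c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  # boundary values go to the lower quartile
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  q1 <- unname(quantile(x, 0.25))
  expect_equal(quartile_rank(c(x, q1))[9L], 0L)
  # rank invariance under monotone transforms
  set.seed(71)
  y <- rnorm(40)
  expect_equal(quartile_rank(y), quartile_rank(exp(y)))
  expect_equal(quartile_rank(y), quartile_rank(2 * y + 7))
  expect_warning(quartile_rank(rep(5, 10)), "distinct")
  expect_error(quartile_rank(c(1, 2, 3)), "at least 8")
})

test_that("wqs_index is the weighted rank sum, bounded and monotone", {
  Q <- rbind(c(3, 3, 3, 3), c(0, 0, 0, 0), c(1, 2, 3, 0))
  expect_equal(wqs_index(rep(0.25, 4), Q), c(3, 0, 1.5))
  expect_equal(wqs_index(c(1, 0, 0, 0), Q), Q[, 1])
  set.seed(72)
  for (rep in 1:10) {
    w <- runif(4); w <- w / sum(w)
    Qr <- matrix(sample(0:3, 60, TRUE), 15, 4)
    oracle <- sapply(1:15, function(j) sum(w * Qr[j, ]))   # double loop
    expect_lt(max(abs(wqs_index(w, Qr) - oracle)), 1e-12)
    expect_true(all(wqs_index(w, Qr) >= 0 &
                      wqs_index(w, Qr) <= 3 + 1e-9))
    # raising any rank never lowers the index
    Q2 <- Qr; j <- sample(15, 1); k <- sample(4, 1)
    Q2[j, k] <- min(Q2[j, k] + 1L, 3L)
    expect_gte(wqs_index(w, Q2)[j], wqs_index(w, Qr)[j])
  }
  expect_error(wqs_index(c(0.5, 0.5), Q), "dimension|components")
  expect_error(wqs_index(c(0.7, 0.5, 0, -0.2), Q), "sum to 1|non-negative")
})

test_that("fit_wqs recovers a dominant planted component on toy data", {
  set.seed(73)
  n <- 60
  S <- matrix(rnorm(4 * n), n, 4)                 # independent scales
  Q <- apply(S, 2, quartile_rank)
  truth <- c(0.7, 0.2, 0.05, 0.05)
  y <- -0.05 * drop(Q %*% truth) + rnorm(n, 0, 0.04)
  f <- fit_wqs(y, S, n_boot = 150, direction = "negative", seed = 7)
  expect_equal(sum(f$weights), 1, tolerance = 1e-9)
  expect_true(all(f$weights >= 0))
  expect_equal(which.max(f$weights), 1L)
  expect_lt(f$p, 0.01)
  expect_lt(f$beta, 0)
  expect_equal(f$contributions_pct, 100 * f$weights)
})

test_that("single-component WQS equals the quartile-rank slope", {
  set.seed(74)
  n <- 50
  s <- rnorm(n)
  q <- quartile_rank(s)
  y <- 0.3 * q + rnorm(n, 0, 0.5)
  f <- fit_wqs(y, matrix(s, ncol = 1), n_boot = 5,
               direction = "positive", seed = 2)
  expect_equal(f$weights, 1)
  ref <- lm(y ~ q)
  expect_equal(f$beta, unname(coef(ref)["q"]), tolerance = 1e-10)
  expect_equal(f$p, summary(ref)$coefficients["q", 4], tolerance = 1e-8)
})

test_that("fit_wqs is deterministic given a seed and validates inputs", {
  set.seed(75)
  S <- matrix(rnorm(4 * 30), 30, 4)
  y <- rnorm(30)
  f1 <- suppressWarnings(fit_wqs(y, S, n_boot = 20, seed = 11))
  f2 <- suppressWarnings(fit_wqs(y, S, n_boot = 20, seed = 11))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$beta, f2$beta)
  expect_error(fit_wqs(y[1:10], S[1:10, ], n_boot = 5), "at least 20")
  expect_error(fit_wqs(c(y[-1], NA), S, n_boot = 5), "missing")
})

test_that("average_bilateral merges pairs by the arithmetic mean", {
  df <- data.frame(subject_id = c("a", "b"), group = c("case", "control"),
                   roi_0 = c(0.08, 0.2), roi_1 = c(0.10, 0.4),
                   roi_2 = c(1, 2))
  class(df) <- c("ec_table", "data.frame")
  out <- average_bilateral(df, list(c(0L, 1L)))
  expect_equal(out$roi_0_1, c(0.09, 0.3))
  expect_equal(ncol(ec_matrix(out)), 2L)
  expect_identical(average_bilateral(df, list()), df)
  expect_error(average_bilateral(df, list(c(0L, 9L))), "unknown ROI")

  # nine hub columns reduce to eight outcomes after merging the pair
  coh <- small_cohort(seed = 76)
  ec <- cohort_ec(coh, preprocess = FALSE)
  merged <- average_bilateral(ec, list(c(13L, 61L)))
  expect_equal(ncol(ec_matrix(merged)), 110L)
  hub_cols <- grep("roi_(13_61|65|81|84|85|104|110|101)$", names(merged))
  expect_length(hub_cols, 8L)
})
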