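test_that("extract_roi_timeseries averages voxels and matches a loop oracle", {
  # 2-voxel ROI with values (1, 3) at t0 -> 2.0
  img <- array(0, c(2, 1, 1, 2))
  img[, 1, 1, 1] <- c(1, 3); img[, 1, 1, 2] <- c(5, 7)
  lab <- array(1L, c(2, 1, 1))
  out <- extract_roi_timeseries(img, lab)
  expect_equal(out[1, ], c(2, 6))

  set.seed(21)
  img <- array(rnorm(4 * 3 * 2 * 5), c(4, 3, 2, 5))
  lab <- array(sample(0:3, 24, replace = TRUE), c(4, 3, 2))
  lab[1, 1, 1] <- 1L  # ensure ROI 1 non-empty
  got <- suppressWarnings(extract_roi_timeseries(img, lab, n_roi = 4L))
  # brute-force voxel loop
  for (r in 1:4) {
    vox <- which(lab == r, arr.ind = TRUE)
    if (nrow(vox) == 0) { expect_true(all(is.na(got[r, ]))); next }
    for (t in 1:5) {
      vals <- apply(vox, 1, function(v) img[v[1], v[2], v[3], t])
      expect_equal(unname(got[r, t]), mean(vals))
    }
  }

  # missing ROI id -> flagged all-NA row
  lab2 <- array(1L, c(4, 3, 2))
  expect_warning(out2 <- extract_roi_timeseries(img, lab2, n_roi = 3L),
                 "no voxels")
  expect_true(all(is.na(out2[2, ])))

  expect_error(extract_roi_timeseries(img, array(1L, c(2, 2, 2))),
               "grid")
})

test_that("AR(1) estimates are unbiased at phi = 0 and recover phi = 0.5", {
  set.seed(31)
  n_rep <- 25L; t_len <- 200L
  motion <- matrix(rnorm(6 * t_len), 6, t_len)
  phis0 <- replicate(n_rep, {
    raw <- matrix(rnorm(4 * t_len), 4, t_len)
    mean(prewhiten_ar1(raw, motion)$ar1_per_roi)
  })
  expect_lt(abs(mean(phis0)), 0.03)

  phis5 <- replicate(n_rep, {
    raw <- t(replicate(4, as.numeric(
      arima.sim(list(ar = 0.5), t_len, sd = sqrt(0.75)))))
    mean(prewhiten_ar1(raw, motion)$ar1_per_roi)
  })
  expect_lt(abs(mean(phis5) - 0.5), 0.05)
})

test_that("prewhitening output has length T-1 and handles degenerate rows", {
  set.seed(32)
  t_len <- 50L
  raw <- rbind(rnorm(t_len), rep(2, t_len))
  motion <- matrix(rnorm(6 * t_len), 6, t_len)
  expect_warning(pw <- prewhiten_ar1(raw, motion), "constant")
  expect_equal(dim(pw$cleaned), c(2L, t_len - 1L))
  expect_equal(pw$ar1_per_roi[2L], 0)
  expect_true(pw$degenerate[2L])

  expect_error(prewhiten_ar1(raw[, 1:8], motion[, 1:8]), "10 time points")
  expect_error(prewhiten_ar1(raw, rbind(motion, motion[1, ] * 2)),
               "rank deficient")
})

test_that("whitening reduces lag-1 autocorrelation on AR(1) fixtures", {
  lag1 <- function(m) {
    mean(abs(apply(m, 1, function(x) cor(x[-1], x[-length(x)]))))
  }
  set.seed(33)
  reduced <- replicate(10, {
    raw <- t(replicate(6, as.numeric(
      arima.sim(list(ar = 0.45), 150, sd = 1))))
    motion <- matrix(rnorm(6 * 150), 6, 150)
    pw <- prewhiten_ar1(raw, motion)
    lag1(pw$cleaned) < lag1(raw)
  })
  expect_gte(mean(reduced), 0.9)
})

test_that("remove_confounds equals the normal-equations oracle and is orthogonal", {
  set.seed(34)
  t_len <- 60L
  y <- matrix(rnorm(5 * t_len), 5, t_len)
  motion <- matrix(rnorm(6 * t_len), 6, t_len)
  wm <- rnorm(t_len); csf <- rnorm(t_len)
  out <- remove_confounds(y, motion, wm, csf)
  X <- cbind(1, t(motion), wm, csf)
  beta <- solve(crossprod(X), crossprod(X, t(y)))   # normal equations
  oracle <- t(t(y) - X %*% beta)
  expect_lt(max(abs(out - oracle)), 1e-10)
  for (j in 2:ncol(X))
    expect_lt(max(abs(cor(t(out), X[, j]))), 1e-10)

  # all-zero confounds: residual equals the demeaned input
  out0 <- suppressWarnings(remove_confounds(y, matrix(0, 6, t_len),
                                            rep(0, t_len), rep(0, t_len)))
  expect_equal(out0, y - rowMeans(y), tolerance = 1e-12)

  # ROI equal to the WM series vanishes
  y2 <- rbind(wm, rnorm(t_len))
  out2 <- remove_confounds(y2, motion, wm, csf)
  expect_lt(max(abs(out2[1, ])), 1e-10)

  # confounds longer than the whitened series are trimmed from the front
  outtrim <- remove_confounds(y[, -1], motion, wm, csf)
  expect_equal(dim(outtrim), c(5L, t_len - 1L))
})
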