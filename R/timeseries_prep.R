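# ---- Time-series preparation ----------------------------------------------
# Two-step pre-whitening GLM: (1) filter raw series against motion, estimate
# AR(1) on the residuals, remove the AR(1) structure from the raw data;
# (2) regress out motion + WM + CSF from the whitened series.

#' Extract mean ROI time series from a 4D volume and a label image
#'
#' Row r of the output is, per time point, the mean over voxels carrying
#' label r (1-based label value maps to 0-based ROI index r - 1; 0 is
#' background).
#'
#' @param image 4D numeric array (x, y, z, time).
#' @param labels 3D integer array on the same voxel grid; values in
#'   0..n_roi.
#' @param n_roi Number of ROIs expected (default: max label).
#' @return Numeric matrix, `n_roi` x `time`. ROIs with no voxels get an
#'   all-`NA` row and a warning.
#' @export
extract_roi_timeseries <- function(image, labels, n_roi = max(labels)) {
  dimg <- dim(image)
  if (length(dimg) != 4L) stop("image must be a 4D array")
  if (!identical(dim(labels), dimg[1:3]))
    stop("label image grid ", paste(dim(labels), collapse = "x"),
         " does not match image grid ", paste(dimg[1:3], collapse = "x"))
  nt <- dimg[4L]
  lab <- as.integer(labels)
  if (any(lab < 0L) || any(lab > n_roi))
    stop("label values must lie in 0..", n_roi)
  mat <- matrix(image, nrow = prod(dimg[1:3]), ncol = nt)
  out <- matrix(NA_real_, nrow = n_roi, ncol = nt)
  counts <- tabulate(lab, nbins = n_roi)
  # column sums within each label via rowsum on the voxel-by-time matrix
  keep <- lab > 0L
  sums <- rowsum(mat[keep, , drop = FALSE], group = lab[keep])
  got <- as.integer(rownames(sums))
  out[got, ] <- sums / counts[got]
  empty <- which(counts == 0L)
  if (length(empty))
    warning("ROI(s) with no voxels, rows set to NA: ",
            paste(empty - 1L, collapse = ", "), " (0-based)")
  rownames(out) <- paste0("roi_", seq_len(n_roi) - 1L)
  out
}

#' Pre-whiten ROI time series with a per-ROI AR(1) model
#'
#' Step 1 regresses each ROI series on an intercept plus the six motion
#' parameters and keeps the residuals. The lag-1 autoregressive coefficient
#' phi is estimated per ROI by ordinary least squares on those demeaned
#' residuals. The *raw* series is then filtered as
#' `y[t] - phi * y[t-1]`, dropping the first time point, so a length-T
#' input returns a length T-1 whitened matrix.
#'
#' @param raw ROI x time numeric matrix.
#' @param motion 6 x time numeric matrix of motion parameters.
#' @return A list of class `prewhiten_result`:
#'   `cleaned` (ROI x (T-1) whitened matrix), `ar1_per_roi` (phi per ROI,
#'   clipped to (-0.99, 0.99) with a warning if the estimate leaves (-1,1)),
#'   `confound_r2` (fraction of raw variance removed by the motion fit),
#'   `degenerate` (logical per ROI; constant series get phi = 0).
#' @export
prewhiten_ar1 <- function(raw, motion) {
  raw <- as.matrix(raw)
  nt <- ncol(raw)
  if (nt <= 10L) stop("need more than 10 time points, got ", nt)
  if (anyNA(raw)) stop("raw matrix contains missing values")
  motion <- as.matrix(motion)
  if (ncol(motion) != nt)
    stop("motion length ", ncol(motion), " != time length ", nt)
  X <- cbind(1, t(motion))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("motion design is rank deficient")
  Y <- t(raw)                       # time x ROI
  res <- qr.resid(qx, Y)            # step 1 residuals
  fitted_var <- apply(Y, 2, stats::var) # total variance per ROI
  resid_var <- colSums(res^2) / (nt - 1)
  confound_r2 <- ifelse(fitted_var > 0, pmax(0, 1 - resid_var / fitted_var), 0)

  # step 2: lag-1 OLS on demeaned residuals
  rc <- sweep(res, 2, colMeans(res))
  num <- colSums(rc[-1L, , drop = FALSE] * rc[-nt, , drop = FALSE])
  den <- colSums(rc[-nt, , drop = FALSE]^2)
  degenerate <- den < .Machine$double.eps * nt
  phi <- ifelse(degenerate, 0, num / pmax(den, .Machine$double.eps))
  if (any(degenerate))
    warning("constant ROI series, AR(1) set to 0 for ROI row(s): ",
            paste(which(degenerate), collapse = ", "))
  out_of_range <- abs(phi) >= 1
  if (any(out_of_range)) {
    warning("|phi| >= 1 estimate clipped to +/-0.99 for ROI row(s): ",
            paste(which(out_of_range), collapse = ", "))
    phi <- pmin(pmax(phi, -0.99), 0.99)
  }
  cleaned <- raw[, -1L, drop = FALSE] - raw[, -nt, drop = FALSE] * phi
  structure(list(cleaned = cleaned, ar1_per_roi = phi,
                 confound_r2 = confound_r2, degenerate = degenerate),
            class = "prewhiten_result")
}

#' Regress nuisance confounds out of whitened series
#'
#' Residualizes each ROI series on an intercept, the six motion parameters,
#' and the white-matter and CSF signals. Confound series longer than the
#' whitened matrix are trimmed from the front (the whitening filter drops
#' the first time point).
#'
#' @param whitened ROI x time matrix (output of [prewhiten_ar1()]).
#' @param motion 6 x time motion matrix (time length T or T+1).
#' @param wm,csf Numeric vectors (length T or T+1).
#' @return ROI x time residual matrix, orthogonal to every confound.
#' @export
remove_confounds <- function(whitened, motion, wm, csf) {
  whitened <- as.matrix(whitened)
  nt <- ncol(whitened)
  trim <- function(x, what) {
    x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
    extra <- ncol(x) - nt
    if (extra < 0L) stop(what, " shorter than whitened series")
    if (extra > 0L) x <- x[, -(seq_len(extra)), drop = FALSE]
    x
  }
  C <- rbind(trim(motion, "motion"), trim(wm, "wm"), trim(csf, "csf"))
  X <- cbind(1, t(C))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("collinear confounds: design rank ", qx$rank, " < ", ncol(X),
            "; condition number ", format(kappa(X), digits = 3),
            "; dependent columns dropped")
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  t(qr.resid(qx, t(whitened)))
}
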