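# ---- Weighted quantile sum regression of the symptom mixture ---------------

#' Quartile-rank a numeric column
#'
#' Assigns each value an integer rank 0..3 by sample-quartile membership
#' (type-7 quantiles). Values equal to a boundary go to the lower quartile.
#' Monotone transforms of the input leave the ranks unchanged.
#'
#' @param x Numeric vector with at least 8 non-missing values.
#' @return Integer vector of ranks in 0..3 (`NA` preserved).
#' @export
quartile_rank <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 8L) stop("need at least 8 non-missing values")
  if (length(unique(x[ok])) < 4L)
    warning("fewer than 4 distinct values; ranks degrade to the ",
            "available distinct levels")
  qs <- stats::quantile(x[ok], probs = c(0.25, 0.5, 0.75), names = FALSE)
  out <- rep(NA_integer_, length(x))
  out[ok] <- rowSums(outer(x[ok], qs, ">"))
  out
}

#' Weighted quantile sum index
#'
#' `index_j = sum_i w_i * q_ij` over the mixture components; with weights
#' on the simplex and quartile ranks in 0..3 the index is bounded in
#' [0, 3] and monotone non-decreasing in every rank.
#'
#' @param weights Non-negative weights summing to 1.
#' @param quartiles Subjects x components integer rank matrix.
#' @return Numeric per-subject index.
#' @export
wqs_index <- function(weights, quartiles) {
  quartiles <- as.matrix(quartiles)
  if (length(weights) != ncol(quartiles))
    stop("weight length ", length(weights), " != number of components ",
         ncol(quartiles))
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  drop(quartiles %*% weights)
}

# t statistic of the index term in y ~ intercept + covars + Q %*% w,
# computed on pre-residualized inputs (ry, rQ residual to the nuisance
# design), df = residual df of the full model.
.index_t <- function(w, ry, rQ, df) {
  rz <- drop(rQ %*% w)
  szz <- sum(rz^2)
  if (szz < 1e-12) return(0)
  slope <- sum(rz * ry) / szz
  rss <- sum(ry^2) - slope^2 * szz
  se <- sqrt(max(rss, 0) / df / szz)
  if (se == 0) return(sign(slope) * Inf)
  slope / se
}

softmax_weights <- function(theta) {
  e <- exp(c(0, theta) - max(0, theta))
  e / sum(e)
}

# One constrained weight estimation: maximize the signed index association
# over the weight simplex via softmax reparameterization, multi-start
# Nelder-Mead. `dsign` = -1 seeks the most negative t, +1 the most positive.
.estimate_weights <- function(ry, rQ, df, dsign, n_starts, seed_starts) {
  c1 <- ncol(rQ) - 1L
  # minimize -dsign * t: drives t toward the requested sign
  objective <- function(theta) -dsign * .index_t(softmax_weights(theta),
                                                 ry, rQ, df)
  best <- NULL
  starts <- c(list(rep(0, c1)), lapply(seq_len(n_starts - 1L),
                                       function(i) seed_starts[, i]))
  for (st in starts) {
    o <- tryCatch(stats::optim(st, objective, method = "Nelder-Mead",
                               control = list(reltol = 1e-8,
                                              maxit = 2000)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) return(NULL)
  list(weights = softmax_weights(best$par), value = best$value)
}

#' Fit a weighted quantile sum regression
#'
#' Two-step WQS: (1) over `n_boot` bootstrap resamples, estimate
#' non-negative sum-to-one component weights maximizing the signed
#' association between the weighted quartile index and the outcome in a
#' covariate-adjusted linear model (softmax reparameterization of the
#' simplex, multi-start Nelder-Mead); (2) aggregate weights across
#' bootstraps and test the resulting index on the full sample in
#' `outcome ~ index + covariates`.
#'
#' @param outcome Numeric outcome (e.g. hub centrality), analysis sample
#'   only (n >= 20).
#' @param scales Data frame or matrix of mixture components (columns are
#'   the four symptom subscales); quartiled internally on the full
#'   analysis sample before resampling.
#' @param covariates Optional data frame/matrix of adjustment covariates.
#' @param n_boot Bootstrap resamples for weight estimation (default 5000).
#' @param direction `"negative"` (default) or `"positive"`: the sign of
#'   association the weights are trained toward. Set explicitly; the
#'   default matches a deficit hypothesis (higher symptom burden, lower
#'   centrality).
#' @param seed Integer seed.
#' @param aggregate `"signal"` (default): mean of weights over bootstraps
#'   whose index |t| exceeds `signal_t`, falling back to all bootstraps
#'   with a warning when none qualify; `"mean"`: plain mean.
#' @param signal_t Threshold for the signal-weighted aggregation.
#' @param n_starts Multi-starts per bootstrap optimization.
#' @return A `wqs_fit` list: `beta`, `se`, `p`, `weights` (sum 1),
#'   `contributions_pct`, `index` (per subject), `covariate_coefficients`,
#'   `n_boot`, `n_dropped`, `n_signal`, `direction`, `seed`.
#' @export
fit_wqs <- function(outcome, scales, covariates = NULL, n_boot = 5000L,
                    direction = c("negative", "positive"), seed = 1L,
                    aggregate = c("signal", "mean"), signal_t = 2,
                    n_starts = 5L) {
  direction <- match.arg(direction)
  aggregate <- match.arg(aggregate)
  y <- as.numeric(outcome)
  Qraw <- as.matrix(scales)
  n <- length(y)
  if (n < 20L) stop("need at least 20 subjects, got ", n)
  if (nrow(Qraw) != n) stop("scales and outcome lengths differ")
  if (anyNA(y) || anyNA(Qraw)) stop("missing values in outcome or scales")
  Q <- apply(Qraw, 2, quartile_rank)
  cmp <- ncol(Q)
  Zfull <- matrix(1, n, 1L)
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "double"
    const <- apply(C, 2, function(x) stats::sd(x) == 0)
    if (any(const)) {
      warning("constant covariate(s) dropped: ",
              paste(colnames(C)[const], collapse = ", "))
      C <- C[, !const, drop = FALSE]
    }
    covariates <- if (ncol(C)) as.data.frame(C) else NULL
    if (!is.null(covariates)) Zfull <- cbind(Zfull, C)
  }
  dsign <- if (direction == "negative") -1 else 1

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  W <- matrix(NA_real_, n_boot, cmp)
  tvals <- rep(NA_real_, n_boot)
  df_full <- n - ncol(Zfull) - 1L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    Zb <- Zfull[idx, , drop = FALSE]
    qz <- tryCatch(qr(Zb), error = function(e) NULL)
    if (is.null(qz) || qz$rank < ncol(Zb)) next
    ry <- qr.resid(qz, y[idx])
    rQ <- qr.resid(qz, Q[idx, , drop = FALSE])
    if (cmp == 1L) {
      W[b, ] <- 1
      tvals[b] <- .index_t(1, ry, rQ, length(idx) - ncol(Zb) - 1L)
      next
    }
    seed_starts <- matrix(stats::rnorm((cmp - 1L) * (n_starts - 1L)),
                          cmp - 1L, n_starts - 1L)
    est <- .estimate_weights(ry, rQ, length(idx) - ncol(Zb) - 1L, dsign,
                             n_starts, seed_starts)
    if (is.null(est)) next
    W[b, ] <- est$weights
    tvals[b] <- .index_t(est$weights, ry, rQ, length(idx) - ncol(Zb) - 1L)
  }
  ok <- !is.na(tvals)
  n_dropped <- sum(!ok)
  if (n_dropped > n_boot / 2)
    stop("more than half of the bootstrap fits failed (", n_dropped,
         " of ", n_boot, ")")
  use <- ok
  n_signal <- NA_integer_
  if (aggregate == "signal") {
    sig <- ok & abs(tvals) >= signal_t
    n_signal <- sum(sig)
    if (n_signal == 0L) {
      warning("no bootstrap fit reached |t| >= ", signal_t,
              "; aggregating over all fits")
    } else use <- sig
  }
  w_hat <- colMeans(W[use, , drop = FALSE])
  w_hat <- pmax(w_hat, 0)
  w_hat <- w_hat / sum(w_hat)
  stopifnot(abs(sum(w_hat) - 1) < 1e-9)

  index <- wqs_index(w_hat, Q)
  dfit <- data.frame(y = y, index = index)
  if (!is.null(covariates))
    dfit <- cbind(dfit, as.data.frame(covariates))
  fit <- stats::lm(y ~ ., data = dfit)
  sm <- summary(fit)$coefficients
  cov_terms <- setdiff(rownames(sm), c("(Intercept)", "index"))
  structure(list(beta = sm["index", 1], se = sm["index", 2],
                 p = sm["index", 4], weights = w_hat,
                 contributions_pct = 100 * w_hat, index = index,
                 covariate_coefficients = sm[cov_terms, 1],
                 n_boot = as.integer(n_boot),
                 n_dropped = as.integer(n_dropped),
                 n_signal = n_signal, direction = direction,
                 seed = as.integer(seed)),
            class = "wqs_fit")
}

#' Average bilateral ROI columns of a centrality table
#'
#' Each (left, right) pair is replaced by a single column holding the
#' arithmetic mean of the two, named `roi_<L>_<R>`; the table width drops
#' by one per pair.
#'
#' @param ec An `ec_table`.
#' @param pairs List of length-2 integer vectors of 0-based ROI indices.
#' @return The reduced `ec_table`.
#' @export
average_bilateral <- function(ec, pairs) {
  if (!length(pairs)) return(ec)
  df <- as.data.frame(ec)
  for (pr in pairs) {
    cols <- paste0("roi_", pr)
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop("unknown ROI column(s): ",
                           paste(miss, collapse = ", "))
    merged <- rowMeans(df[, cols])
    pos <- min(match(cols, names(df)))
    df[[paste0("roi_", pr[1L], "_", pr[2L])]] <- merged
    df <- df[, setdiff(names(df), cols), drop = FALSE]
    # keep merged column near its original position
    nn <- names(df)
    merged_col <- paste0("roi_", pr[1L], "_", pr[2L])
    rest <- setdiff(nn, merged_col)
    df <- df[, append(rest, merged_col, after = pos - 1L), drop = FALSE]
  }
  class(df) <- c("ec_table", "data.frame")
  df
}

#' @export
print.wqs_fit <- function(x, ...) {
  cat("WQS fit (", x$direction, " direction, ", x$n_boot,
      " bootstraps):\n", sep = "")
  cat(sprintf("  beta = %.4g (SE %.3g), p = %.4g\n", x$beta, x$se, x$p))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = ", "),
      "\n")
  invisible(x)
}
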