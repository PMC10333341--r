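# ---- Permutation FWE test for hubs of differential connectivity ------------

# Closed-form per-ROI group t statistics for Y (n x p) on fixed design X,
# where `col` indexes the coefficient of interest. Returns the t vector.
.group_tstats <- function(qx, XtXinv_col, Y, col, df) {
  coefs <- qr.coef(qx, Y)                       # k x p
  res <- qr.resid(qx, Y)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * XtXinv_col)
  drop(coefs[col, ] / se)
}

#' Permutation test for group differences in eigenvector centrality
#'
#' Per ROI, fits `EC ~ intercept + group + covariates` by least squares and
#' records the group t statistic. The null distribution is built by the
#' Freedman-Lane scheme: centrality is residualized on the nuisance
#' covariates, the residual rows are permuted jointly across ROIs, the
#' fitted nuisance part is added back, and the full model is refit. Family-
#' wise error is controlled with the max-statistic (Westfall-Young) rule:
#' each ROI's corrected p is the fraction of permutations whose maximum
#' statistic across all ROIs reaches its observed statistic, with the usual
#' +1 smoothing so p is never 0.
#'
#' @param ec An `ec_table` (or plain data frame with `subject_id`, `group`,
#'   `roi_*` columns).
#' @param group Optional explicit binary labels (1 = case); defaults to the
#'   table's `group` column.
#' @param covariates Data frame or matrix of nuisance covariates aligned to
#'   the rows of `ec` (e.g. MDD, psychotropic and opioid use). Constant
#'   columns are dropped with a warning.
#' @param n_perm Number of permutations (default 1000; fewer than 100 draws
#'   a warning).
#' @param alpha Family-wise significance level.
#' @param direction `"control_gt_case"` (default; tests control > case),
#'   `"case_gt_control"`, or `"two_sided"`.
#' @param seed Integer seed for the permutation draws.
#' @return A `hub_test_result` list: `statistic` (per ROI), `fwe_p`,
#'   `hubs` (0-based ROI indices with `fwe_p <= alpha`), `n_perm`,
#'   `direction`, `alpha`, `seed`, and `max_null` (the permutation
#'   max-statistic distribution, for diagnostics).
#' @export
permutation_hub_test <- function(ec, group = NULL, covariates = NULL,
                                 n_perm = 1000L, alpha = 0.05,
                                 direction = c("control_gt_case",
                                               "case_gt_control",
                                               "two_sided"),
                                 seed = 1L) {
  direction <- match.arg(direction)
  Y <- ec_matrix(ec)
  n <- nrow(Y)
  if (is.null(group)) {
    if (is.null(ec$group)) stop("no group labels supplied")
    group <- as.integer(ec$group == "case")
  } else group <- as.integer(as.logical(group))
  if (length(unique(group)) < 2L) stop("need two groups")
  if (min(table(group)) < 2L) stop("need at least 2 subjects per group")
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse null")

  Z <- matrix(1, n, 1L)
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "double"
    const <- apply(C, 2, function(x) stats::sd(x) == 0)
    if (any(const)) {
      warning("constant covariate(s) dropped: ",
              paste(colnames(C)[const], collapse = ", "))
      C <- C[, !const, drop = FALSE]
    }
    if (ncol(C)) Z <- cbind(Z, C)
  }
  # contrast sign: positive statistic means the tested direction
  gsign <- switch(direction, control_gt_case = -1, 1)
  X <- cbind(Z, group = group)
  gcol <- ncol(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design rank deficient (group collinear with covariates?)")
  XtXinv <- chol2inv(qr.R(qx))
  df <- n - ncol(X)
  tobs <- gsign * .group_tstats(qx, XtXinv[gcol, gcol], Y, gcol, df)
  stat_obs <- if (direction == "two_sided") abs(tobs) else tobs

  # Freedman-Lane: nuisance-only fit
  qz <- qr(Z)
  Rz <- qr.resid(qz, Y)
  Hz <- qr.fitted(qz, Y)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  max_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    Ystar <- Hz + Rz[perm, , drop = FALSE]
    tb <- gsign * .group_tstats(qx, XtXinv[gcol, gcol], Ystar, gcol, df)
    max_null[b] <- if (direction == "two_sided") max(abs(tb)) else max(tb)
  }
  fwe_p <- (1 + vapply(stat_obs, function(s) sum(max_null >= s),
                       numeric(1))) / (n_perm + 1)
  hubs <- which(fwe_p <= alpha) - 1L
  structure(list(statistic = stat_obs, fwe_p = fwe_p, hubs = hubs,
                 n_perm = as.integer(n_perm), direction = direction,
                 alpha = alpha, seed = as.integer(seed),
                 max_null = max_null),
            class = "hub_test_result")
}

#' Tabulate hub-test results against a registry
#'
#' One row per detected hub: region name, hemisphere, abbreviation and
#' FWE-corrected p, sorted by p (the printed ROI number is 1-based).
#'
#' @param result A `hub_test_result`.
#' @param registry A `roi_registry` with as many regions as the tested
#'   table had ROI columns.
#' @param all_rois If `TRUE`, report every ROI, not only the hubs.
#' @return Data frame with columns `roi`, `region`, `hemisphere`,
#'   `abbreviation`, `statistic`, `p_fwe`.
#' @export
hub_report <- function(result, registry, all_rois = FALSE) {
  stopifnot(inherits(result, "hub_test_result"))
  if (nrow(registry) != length(result$fwe_p))
    stop("registry has ", nrow(registry), " regions but the test covered ",
         length(result$fwe_p), " ROIs")
  idx0 <- if (all_rois) registry$index else result$hubs
  out <- data.frame(roi = idx0 + 1L,
                    region = registry$name[match(idx0, registry$index)],
                    hemisphere = registry$hemisphere[match(idx0, registry$index)],
                    abbreviation = registry$abbreviation[match(idx0, registry$index)],
                    statistic = result$statistic[idx0 + 1L],
                    p_fwe = result$fwe_p[idx0 + 1L],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_fwe, -abs(out$statistic)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.hub_test_result <- function(x, ...) {
  cat("Permutation hub test:", length(x$fwe_p), "ROIs,", x$n_perm,
      "permutations, direction =", x$direction, "\n")
  cat("Hubs at alpha =", x$alpha, ":",
      if (length(x$hubs)) paste(x$hubs, collapse = ", ") else "none",
      "(0-based)\n")
  invisible(x)
}
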