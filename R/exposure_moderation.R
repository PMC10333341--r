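# ---- Exposure-duration moderation models -----------------------------------

#' Fit exposure-by-diagnosis moderation models per hub
#'
#' For each hub ROI, fits the Gaussian-identity linear model
#' `EC ~ months + psychotropic + opioid + mdd + ptsd + months:ptsd`
#' on the subjects with non-missing exposure months (list-wise dropped and
#' counted). The interaction term tests whether months on site moderates
#' the diagnosis-centrality association.
#'
#' @param ec An `ec_table`.
#' @param phenotypes Phenotype data frame with `subject_id`,
#'   `months_on_site`, `psychotropic`, `opioid`, `mdd`, `ptsd`.
#' @param hub_rois Integer vector of 0-based ROI indices to model.
#' @return List of `moderation_fit` objects, one per hub. Each contains
#'   `roi` (0-based), `coefficients` (estimate, se, ci_lo, ci_hi, p per
#'   term), `vcov`, `r2`, `n_obs`, `n_dropped`, `df_residual`.
#' @export
fit_moderation <- function(ec, phenotypes, hub_rois) {
  Y <- ec_matrix(ec)
  ph <- phenotypes[match(ec$subject_id, phenotypes$subject_id), ,
                   drop = FALSE]
  keep <- !is.na(ph$months_on_site)
  n_dropped <- sum(!keep)
  if (mean(keep) < 0.8)
    warning("more than 20% of subjects lack exposure months (",
            n_dropped, " dropped)")
  if (sum(keep) < 10L) stop("fewer than 10 usable subjects")
  d <- data.frame(months = ph$months_on_site,
                  psychotropic = ph$psychotropic, opioid = ph$opioid,
                  mdd = ph$mdd, ptsd = ph$ptsd)[keep, , drop = FALSE]
  if (stats::sd(d$months) == 0)
    stop("exposure months constant: interaction inestimable")
  covs <- c("psychotropic", "opioid", "mdd")
  const <- covs[vapply(covs, function(v) stats::sd(d[[v]]) == 0, logical(1))]
  if (length(const)) {
    warning("constant covariate(s) dropped: ", paste(const, collapse = ", "))
    covs <- setdiff(covs, const)
  }
  fml <- stats::reformulate(c("months", covs, "ptsd", "months:ptsd"),
                            response = "ec")
  lapply(hub_rois, function(r) {
    d$ec <- Y[keep, r + 1L]
    fit <- stats::lm(fml, data = d)
    kap <- kappa(stats::model.matrix(fit))
    if (kap > 1e8)
      warning("ill-conditioned design for ROI ", r,
              " (condition number ", format(kap, digits = 3), ")")
    sm <- summary(fit)
    co <- stats::coef(sm)
    ci <- stats::confint(fit)
    coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                        se = co[, 2], ci_lo = ci[, 1], ci_hi = ci[, 2],
                        p = co[, 4], stringsAsFactors = FALSE,
                        row.names = NULL)
    structure(list(roi = as.integer(r), coefficients = coefs,
                   vcov = stats::vcov(fit), r2 = sm$r.squared,
                   n_obs = nrow(d), n_dropped = n_dropped,
                   df_residual = fit$df.residual),
              class = "moderation_fit")
  })
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up false-discovery-rate adjustment: sort the m p-values
#' ascending, compute p_(i) * m / i, and enforce monotonicity by a
#' cumulative minimum from the largest down. Order-preserving and
#' idempotent; the largest input maps to itself.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
adjust_pvalues_bh <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Within-case simple slope of exposure months
#'
#' For a moderation fit, the exposure slope within the case group is the
#' sum of the months main effect and the interaction coefficient; its
#' standard error comes from the coefficient covariance.
#'
#' @param fit A `moderation_fit`.
#' @return List with `slope`, `se`, `ci95` (length-2), `p`, `df`.
#' @export
simple_slope <- function(fit) {
  stopifnot(inherits(fit, "moderation_fit"))
  V <- fit$vcov
  terms <- rownames(V)
  im <- match("months", terms)
  ii <- match("months:ptsd", terms)
  if (is.na(im) || is.na(ii))
    stop("fit lacks months and months:ptsd terms")
  b <- fit$coefficients$estimate[match(c("months", "months:ptsd"),
                                       fit$coefficients$term)]
  slope <- sum(b)
  se <- sqrt(V[im, im] + V[ii, ii] + 2 * V[im, ii])
  if (!is.finite(se)) stop("coefficient covariance unavailable")
  tval <- slope / se
  df <- fit$df_residual
  p <- 2 * stats::pt(-abs(tval), df)
  crit <- stats::qt(0.975, df)
  list(slope = slope, se = se, ci95 = c(slope - crit * se, slope + crit * se),
       p = p, df = df)
}

#' Tabulate moderation fits
#'
#' One block per hub in long format, with BH-adjusted interaction p-values
#' across hubs appended.
#'
#' @param fits List of `moderation_fit` (from [fit_moderation()]).
#' @param registry Optional `roi_registry` for region names.
#' @return Data frame with `roi`, `region`, `term`, `estimate`, `ci_lo`,
#'   `ci_hi`, `p`, plus `p_interaction_adj`, `r2` and `n_obs` on the
#'   interaction rows.
#' @export
moderation_report <- function(fits, registry = NULL) {
  p_int <- vapply(fits, function(f)
    f$coefficients$p[f$coefficients$term == "months:ptsd"], numeric(1))
  p_adj <- adjust_pvalues_bh(p_int)
  blocks <- Map(function(f, pa) {
    co <- f$coefficients
    co$roi <- f$roi + 1L
    co$region <- if (!is.null(registry))
      registry$name[match(f$roi, registry$index)] else NA_character_
    co$p_interaction_adj <- ifelse(co$term == "months:ptsd", pa, NA_real_)
    co$r2 <- ifelse(co$term == "months:ptsd", f$r2, NA_real_)
    co$n_obs <- ifelse(co$term == "months:ptsd", f$n_obs, NA_integer_)
    co[, c("roi", "region", "term", "estimate", "ci_lo", "ci_hi", "p",
           "p_interaction_adj", "r2", "n_obs")]
  }, fits, p_adj)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
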