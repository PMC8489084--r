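new_mr_estimate <- function(method, beta, se, n, data, extra = NULL) {
  est <- list(method = method, beta = beta, se = se,
              or = exp(beta),
              ci_low = exp(beta - Z975 * se),
              ci_high = exp(beta + Z975 * se),
              pvalue = two_sided_p(beta / se),
              n_snp = n,
              exposure_name = data$exposure_name,
              outcome_name = data$outcome_name)
  structure(c(est, extra), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: %s -> %s (%d SNP%s)\n", x$method, x$exposure_name,
              x$outcome_name, x$n_snp, if (x$n_snp > 1L) "s" else ""))
  cat(sprintf("  log-odds %.4f (SE %.4f); OR %.3f, 95%% CI %.3f-%.3f, P = %.3g\n",
              x$beta, x$se, x$or, x$ci_low, x$ci_high, x$pvalue))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(exposure = x$exposure_name, outcome = x$outcome_name,
             method = x$method, nsnp = x$n_snp, beta = x$beta, se = x$se,
             or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
             pvalue = x$pvalue, stringsAsFactors = FALSE)
}

#' Wald ratio estimate from a single instrument
#'
#' The per-SNP causal estimate: the outcome effect divided by the exposure
#' effect, with the first-order (delta-method) standard error
#' `se_outcome / |beta_exposure|` that treats the exposure effect as known.
#'
#' @param data an [mr_dataset()].
#' @param rsid which variant to use; may be omitted when the dataset holds
#'   exactly one.
#' @return an `mr_estimate`.
#' @export
mr_wald_ratio <- function(data, rsid = NULL) {
  stopifnot(inherits(data, "mr_dataset"))
  s <- data$snps
  if (is.null(rsid)) {
    if (nrow(s) != 1L)
      stop("mr_wald_ratio: specify `rsid` when the dataset has >1 SNP",
           call. = FALSE)
    i <- 1L
  } else {
    i <- match(rsid, s$rsid)
    if (is.na(i)) stop("mr_wald_ratio: no such rsid: ", rsid, call. = FALSE)
  }
  if (s$beta_exposure[i] == 0)
    stop("mr_wald_ratio: zero exposure beta for ", s$rsid[i], call. = FALSE)
  new_mr_estimate("wald_ratio",
                  beta = s$beta_outcome[i] / s$beta_exposure[i],
                  se = s$se_outcome[i] / abs(s$beta_exposure[i]),
                  n = 1L, data, extra = list(rsid = s$rsid[i]))
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analyzes the per-SNP Wald ratios with first-order inverse-variance
#' weights `w_i = beta_exposure^2 / se_outcome^2`; equivalently, weighted
#' least squares of the outcome betas on the exposure betas through the
#' origin with weights `1/se_outcome^2`. The point estimate is identical in
#' both modes; in `"multiplicative_random"` mode (the default) the standard
#' error is inflated by `max(1, sqrt(Q/(k-1)))` where `Q` is Cochran's
#' statistic, crediting no under-dispersion.
#'
#' @param data an [mr_dataset()]; a single-SNP dataset degrades to the Wald
#'   ratio.
#' @param mode `"multiplicative_random"` or `"fixed"`.
#' @return an `mr_estimate`.
#' @examples
#' mr_ivw(mr_fixture("25OHD"))
#' @export
mr_ivw <- function(data, mode = c("multiplicative_random", "fixed")) {
  stopifnot(inherits(data, "mr_dataset"))
  mode <- match.arg(mode)
  k <- n_snp(data)
  if (k == 1L) {
    est <- mr_wald_ratio(data)
    est$method <- paste0("ivw_", if (mode == "fixed") "fe" else "mre")
    return(est)
  }
  rw <- ratio_weights(data)
  beta <- sum(rw$w * rw$r) / sum(rw$w)
  se_fixed <- sqrt(1 / sum(rw$w))
  q <- sum(rw$w * (rw$r - beta)^2)
  infl <- if (mode == "multiplicative_random") max(1, sqrt(q / (k - 1))) else 1
  new_mr_estimate(if (mode == "fixed") "ivw_fe" else "ivw_mre",
                  beta = beta, se = se_fixed * infl, n = k, data,
                  extra = list(q = q, inflation = infl))
}

# weighted median of ratios r with weights w: sort ascending, form
# cumulative weight midpoints s_i = cumsum(w') - w'/2 with w' normalized,
# and linearly interpolate r against s at s = 0.5
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The 50% point of the inverse-variance-weight-ordered Wald ratios,
#' consistent when at least half of the total weight comes from valid
#' instruments. The standard error is the standard deviation of the
#' estimate over `n_boot` parametric-bootstrap replicates in which each
#' exposure and outcome beta is redrawn from a normal distribution with its
#' observed mean and standard error.
#'
#' @param data an [mr_dataset()] with at least 3 SNPs.
#' @param n_boot number of bootstrap replicates (default 1000; minimum 2).
#' @param seed integer seed for the bootstrap; required, so the estimate is
#'   reproducible.
#' @return an `mr_estimate`.
#' @examples
#' mr_weighted_median(mr_fixture("25OHD"), seed = 42)
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed) {
  stopifnot(inherits(data, "mr_dataset"))
  k <- n_snp(data)
  if (k < 3L)
    stop("mr_weighted_median: need at least 3 SNPs, have ", k, call. = FALSE)
  if (n_boot < 2L)
    stop("mr_weighted_median: n_boot must be at least 2", call. = FALSE)
  if (missing(seed))
    stop("mr_weighted_median: `seed` is required", call. = FALSE)
  rw <- ratio_weights(data)
  beta <- weighted_median_point(rw$r, rw$w)
  s <- data$snps
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      be <- stats::rnorm(k, s$beta_exposure, s$se_exposure)
      bo <- stats::rnorm(k, s$beta_outcome, s$se_outcome)
      be[be == 0] <- .Machine$double.eps  # guard: resampled beta exactly 0
      weighted_median_point(bo / be, be^2 / s$se_outcome^2)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", beta = beta, se = stats::sd(boot),
                  n = k, data,
                  extra = list(n_boot = n_boot, seed = seed))
}

# weighted least squares of beta_outcome on beta_exposure, weights
# 1/se_outcome^2, solved from the normal equations; `intercept = FALSE`
# gives the through-the-origin fit (equal to IVW) and exists for testing
egger_wls <- function(data, intercept = TRUE) {
  s <- data$snps
  w <- 1 / s$se_outcome^2
  x <- s$beta_exposure
  y <- s$beta_outcome
  X <- if (intercept) cbind(1, x) else cbind(x)
  XtWX <- unname(crossprod(X, w * X))
  est <- unname(drop(solve(XtWX, crossprod(X, w * y))))
  fitted <- drop(X %*% est)
  rss_w <- sum(w * (y - fitted)^2)
  dfres <- length(y) - ncol(X)
  se_unscaled <- unname(sqrt(diag(solve(XtWX))))
  list(coef = drop(est), se_unscaled = se_unscaled, rss_w = rss_w,
       df = dfres)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with a
#' free intercept (weights `1/se_outcome^2`). The slope is a
#' pleiotropy-robust causal estimate under the InSIDE assumption; a
#' non-zero intercept measures average directional pleiotropy. Both
#' standard errors carry a multiplicative over-dispersion inflation
#' `max(1, sqrt(RSS_w/(k-2)))`; p-values are two-sided from the t
#' distribution with `k - 2` degrees of freedom, the appropriate small-k
#' reference for a two-parameter weighted regression. Confidence intervals
#' use the conventional 1.96 normal quantile, as reported MR estimates in
#' this field usually do.
#'
#' @param data an [mr_dataset()] with at least 3 SNPs and non-constant
#'   exposure betas.
#' @return an object of class `mr_egger`: a list with elements `slope` (an
#'   `mr_estimate`) and `intercept` (estimate, se, pvalue).
#' @examples
#' fit <- mr_egger(mr_fixture("25OHD"))
#' fit$intercept$pvalue
#' @export
mr_egger <- function(data) {
  stopifnot(inherits(data, "mr_dataset"))
  k <- n_snp(data)
  if (k < 3L)
    stop("mr_egger: need at least 3 SNPs, have ", k, call. = FALSE)
  if (stats::sd(data$snps$beta_exposure) < 1e-12 * max(abs(data$snps$beta_exposure)))
    stop("mr_egger: exposure betas are collinear with the intercept ",
         "(all equal); the slope is unidentifiable", call. = FALSE)
  fit <- egger_wls(data, intercept = TRUE)
  infl <- max(1, sqrt(fit$rss_w / fit$df))
  se <- fit$se_unscaled * infl
  t_p <- function(z) pmax(2 * stats::pt(-abs(z), df = fit$df),
                          .Machine$double.xmin)
  slope <- new_mr_estimate("egger_slope", beta = fit$coef[2], se = se[2],
                           n = k, data,
                           extra = list(inflation = infl))
  slope$pvalue <- t_p(fit$coef[2] / se[2])
  intercept <- list(estimate = fit$coef[1], se = se[1],
                    pvalue = t_p(fit$coef[1] / se[1]))
  structure(list(slope = slope, intercept = intercept),
            class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4f (SE %.4f), P = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  invisible(x)
}
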