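#' Fit the full suite of two-sample MR estimators and diagnostics
#'
#' The package's central fitting function. Given a harmonized dataset it
#' runs the IVW estimator (the primary analysis) together with the
#' pleiotropy-robust weighted-median and MR-Egger estimators, Cochran's Q,
#' the Egger intercept test, the leave-one-out analysis, and (with at
#' least 4 SNPs) MR-PRESSO. Methods whose instrument-count preconditions
#' fail are recorded as explicit skips, never silently dropped.
#'
#' @param data an [mr_dataset()].
#' @param seed integer seed driving the weighted-median bootstrap and the
#'   MR-PRESSO simulations; required for a reproducible fit.
#' @param ivw_mode `"multiplicative_random"` (default) or `"fixed"`.
#' @param n_boot bootstrap replicates for the weighted median.
#' @param n_sim simulations for MR-PRESSO.
#' @param outlier_alpha MR-PRESSO outlier significance level (before the
#'   Bonferroni division by the SNP count).
#' @return an object of class `mr_fit` with components `data`, `estimates`
#'   (named list of `mr_estimate`s), `heterogeneity`, `egger_intercept`,
#'   `leave_one_out`, `single_snp`, `presso`, `skipped` (named character
#'   vector of skip reasons), and the call configuration. Supports
#'   `print()`, `summary()`, `coef()`, `confint()`, `plot()`,
#'   `residuals()` and `simulate()`.
#' @examples
#' fit <- mr_fit(mr_fixture("25OHD"), seed = 42, n_sim = 200)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(data, seed, ivw_mode = c("multiplicative_random", "fixed"),
                   n_boot = 1000, n_sim = 1000, outlier_alpha = 0.05) {
  stopifnot(inherits(data, "mr_dataset"))
  if (missing(seed)) stop("mr_fit: `seed` is required", call. = FALSE)
  ivw_mode <- match.arg(ivw_mode)
  k <- n_snp(data)
  estimates <- list()
  skipped <- character(0)

  estimates$ivw <- mr_ivw(data, mode = ivw_mode)

  if (k >= 3L) {
    estimates$weighted_median <-
      mr_weighted_median(data, n_boot = n_boot, seed = seed)
    eg <- mr_egger(data)
    estimates$egger <- eg$slope
    egger_intercept <- eg$intercept
  } else {
    skipped["weighted_median"] <- skipped["egger"] <-
      sprintf("needs >= 3 SNPs, have %d", k)
    egger_intercept <- NULL
  }

  heterogeneity <- if (k >= 2L) mr_cochran_q(data) else {
    skipped["heterogeneity"] <- sprintf("needs >= 2 SNPs, have %d", k)
    NULL
  }
  leave_one_out <- if (k >= 3L) mr_leave_one_out(data, mode = ivw_mode) else {
    skipped["leave_one_out"] <- sprintf("needs >= 3 SNPs, have %d", k)
    NULL
  }
  presso <- if (k >= 4L) {
    mr_presso(data, n_sim = n_sim, seed = seed,
              outlier_alpha = outlier_alpha)
  } else {
    skipped["presso"] <- sprintf("needs >= 4 SNPs, have %d", k)
    NULL
  }
  if (!is.null(presso) && !is.null(presso$corrected))
    estimates$presso_corrected <- presso$corrected

  structure(list(data = data, estimates = estimates,
                 heterogeneity = heterogeneity,
                 egger_intercept = egger_intercept,
                 leave_one_out = leave_one_out,
                 single_snp = mr_single_snp(data),
                 presso = presso, skipped = skipped,
                 config = list(seed = seed, ivw_mode = ivw_mode,
                               n_boot = n_boot, n_sim = n_sim,
                               outlier_alpha = outlier_alpha)),
            class = "mr_fit")
}

#' Collect a fit's estimates as a tidy data frame
#' @param x an `mr_fit`.
#' @param ... unused.
#' @return data frame, one row per method.
#' @export
as.data.frame.mr_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(x$estimates, as.data.frame))
  rownames(out) <- NULL
  out
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d SNPs)\n\n",
              x$data$exposure_name, x$data$outcome_name, n_snp(x$data)))
  tab <- as.data.frame(x)
  tab$or <- sprintf("%.3f", tab$or)
  tab$ci <- sprintf("%.3f-%.3f", tab$ci_low, tab$ci_high)
  tab$pvalue <- sprintf("%.3g", tab$pvalue)
  print(tab[c("method", "nsnp", "or", "ci", "pvalue")], row.names = FALSE)
  if (!is.null(x$heterogeneity))
    cat(sprintf("\nCochran's Q = %.2f (df %d), P = %.3f",
                x$heterogeneity$q, x$heterogeneity$df,
                x$heterogeneity$pvalue))
  if (!is.null(x$egger_intercept))
    cat(sprintf("; Egger intercept P = %.3f", x$egger_intercept$pvalue))
  if (!is.null(x$presso))
    cat(sprintf("\nMR-PRESSO global P = %.3g (%s)", x$presso$global_pvalue,
                if (length(x$presso$outlier_rsids))
                  paste("outliers:",
                        paste(x$presso$outlier_rsids, collapse = ", "))
                else "no outliers"))
  cat("\n")
  if (length(x$skipped))
    cat("skipped:", paste(names(x$skipped), x$skipped, sep = ": ",
                          collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$leave_one_out)) {
    cat("\nLeave-one-out (IVW):\n")
    loo <- object$leave_one_out
    loo$or <- sprintf("%.3f", loo$or)
    loo$pvalue <- sprintf("%.3g", loo$pvalue)
    print(loo[c("dropped_rsid", "nsnp", "or", "pvalue")], row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "beta")
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$estimates
  if (!missing(parm)) est <- est[parm]
  out <- t(vapply(est, function(e)
    c(e$beta - z * e$se, e$beta + z * e$se), numeric(2)))
  colnames(out) <- sprintf("%g %%", c((1 - level) / 2,
                                      1 - (1 - level) / 2) * 100)
  out
}

#' Residuals of the fitted IVW model
#'
#' Outcome-scale residuals `beta_outcome - beta_ivw * beta_exposure`, raw
#' or standardized by `se_outcome`.
#'
#' @param object an `mr_fit`.
#' @param type `"response"` or `"standardized"`.
#' @param ... unused.
#' @return named numeric vector, one element per SNP.
#' @export
residuals.mr_fit <- function(object, type = c("response", "standardized"),
                             ...) {
  type <- match.arg(type)
  s <- object$data$snps
  res <- s$beta_outcome - object$estimates$ivw$beta * s$beta_exposure
  if (type == "standardized") res <- res / s$se_outcome
  stats::setNames(res, s$rsid)
}

#' Simulate summary-statistic datasets from a fitted IVW model
#'
#' Parametric draws under the fitted model: exposure betas are redrawn
#' about their observed values and outcome betas about
#' `beta_ivw * beta_exposure`, each with the observed standard errors.
#'
#' @param object an `mr_fit`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` [mr_dataset()]s.
#' @export
simulate.mr_fit <- function(object, nsim = 1, seed = 1L, ...) {
  s <- object$data$snps
  k <- nrow(s)
  b <- object$estimates$ivw$beta
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      d <- s
      d$beta_exposure <- stats::rnorm(k, s$beta_exposure, s$se_exposure)
      d$beta_outcome <- stats::rnorm(k, b * d$beta_exposure, s$se_outcome)
      mr_dataset(d, object$data$exposure_name, object$data$outcome_name)
    })
  })
}

#' Forest-style plot of per-SNP ratios and method estimates
#'
#' Base-graphics forest plot: each instrument's Wald ratio with a 95%
#' interval, followed by the pooled estimates of every fitted method.
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.mr_fit <- function(x, ...) {
  ss <- x$single_snp
  est <- as.data.frame(x)
  labs <- c(ss$rsid, paste0("[", est$method, "]"))
  beta <- c(ss$ratio, est$beta)
  lo <- c(ss$ratio - Z975 * ss$se, est$beta - Z975 * est$se)
  hi <- c(ss$ratio + Z975 * ss$se, est$beta + Z975 * est$se)
  n <- length(labs)
  ypos <- rev(seq_len(n))
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(beta, ypos, xlim = range(lo, hi), ylim = c(0.5, n + 0.5),
                 yaxt = "n", ylab = "", pch = 19,
                 xlab = "log-odds per SD of exposure",
                 main = sprintf("%s -> %s", x$data$exposure_name,
                                x$data$outcome_name), ...)
  graphics::segments(lo, ypos, hi, ypos)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = ypos, labels = labs, las = 1, cex.axis = 0.8)
  invisible(x)
}
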