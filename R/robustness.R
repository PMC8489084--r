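#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of the per-SNP Wald ratios from the
#' IVW pooled estimate, with the same first-order weights as [mr_ivw()].
#' Under homogeneity Q is chi-square with `k - 1` degrees of freedom; the
#' p-value is the upper tail.
#'
#' @param data an [mr_dataset()] with at least 2 SNPs.
#' @return a list of class `mr_heterogeneity`: `q`, `df`, `pvalue`.
#' @examples
#' mr_cochran_q(mr_fixture("25OHD"))
#' @export
mr_cochran_q <- function(data) {
  stopifnot(inherits(data, "mr_dataset"))
  k <- n_snp(data)
  if (k < 2L)
    stop("mr_cochran_q: need at least 2 SNPs, have ", k, call. = FALSE)
  rw <- ratio_weights(data)
  beta <- sum(rw$w * rw$r) / sum(rw$w)
  q <- sum(rw$w * (rw$r - beta)^2)
  structure(list(q = q, df = k - 1L,
                 pvalue = max(stats::pchisq(q, k - 1L, lower.tail = FALSE),
                              .Machine$double.xmin)),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (df %d), P = %.3g\n", x$q, x$df, x$pvalue))
  invisible(x)
}

#' Per-SNP ratio table (funnel/forest coordinates)
#'
#' The Wald ratio, its standard error, and the precision `1/SE` for every
#' instrument. Plotting precision against ratio gives the funnel plot used
#' to inspect heterogeneity visually; the table is exported rather than
#' drawn.
#'
#' @param data an [mr_dataset()].
#' @return data frame with columns `rsid`, `ratio`, `se`, `precision`.
#' @export
mr_single_snp <- function(data) {
  stopifnot(inherits(data, "mr_dataset"))
  rw <- ratio_weights(data)
  se <- 1 / sqrt(rw$w)
  data.frame(rsid = rw$rsid, ratio = rw$r, se = se, precision = 1 / se,
             stringsAsFactors = FALSE)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate `k` times, each time with one instrument
#' removed, to reveal estimates driven disproportionally by a single SNP.
#'
#' @param data an [mr_dataset()] with at least 3 SNPs.
#' @param mode IVW mode passed to [mr_ivw()].
#' @return data frame with one row per dropped SNP: `dropped_rsid`,
#'   `nsnp`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `pvalue`.
#' @examples
#' loo <- mr_leave_one_out(mr_fixture("25OHD"))
#' loo[loo$dropped_rsid == "rs3755967", "or"]
#' @export
mr_leave_one_out <- function(data, mode = "multiplicative_random") {
  stopifnot(inherits(data, "mr_dataset"))
  k <- n_snp(data)
  if (k < 3L)
    stop("mr_leave_one_out: need at least 3 SNPs, have ", k, call. = FALSE)
  rows <- lapply(seq_len(k), function(i) {
    est <- mr_ivw(mr_dataset(data$snps[-i, , drop = FALSE],
                             data$exposure_name, data$outcome_name),
                  mode = mode)
    cbind(data.frame(dropped_rsid = data$snps$rsid[i],
                     stringsAsFactors = FALSE),
          as.data.frame(est)[c("nsnp", "beta", "se", "or", "ci_low",
                               "ci_high", "pvalue")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MR-PRESSO: global heterogeneity test and outlier correction
#'
#' The observed statistic is the weighted residual sum of squares
#' `RSS = sum_i w_i (beta_out_i - bhat_(-i) * beta_exp_i)^2` with
#' `w_i = 1/se_out_i^2`, where `bhat_(-i)` is the fixed-effect IVW estimate
#' computed without SNP i. Its null distribution is built from `n_sim`
#' parametric simulations of a homogeneous dataset: draws
#' `beta_exp* ~ N(beta_exp_i, se_exp_i)` and
#' `beta_out* ~ N(bhat_ivw beta_exp_i, se_out_i)` around the common pooled
#' slope, with the statistic recomputed in full (leave-one-out slopes
#' included) on each simulated dataset. Because the statistic is invariant
#' to the common slope, this parametric bootstrap is calibrated and the
#' simulated null does not inherit contamination from any outlier via the
#' per-SNP leave-one-out means. The global p-value uses the add-one
#' estimator `(1 + #\{sim >= obs\})/(n_sim + 1)` and so is never zero.
#' Per-SNP p-values come from each SNP's simulated residual distribution
#' and are flagged as outliers below `outlier_alpha / k` (Bonferroni); when
#' any SNP is flagged, an outlier-corrected IVW estimate on the remaining
#' SNPs is returned.
#'
#' @param data an [mr_dataset()] with at least 4 SNPs.
#' @param n_sim number of null simulations (minimum 100).
#' @param seed integer seed; required.
#' @param outlier_alpha family-wise significance level for the per-SNP
#'   outlier test before the Bonferroni division by `k`.
#' @param distortion if `TRUE`, also bootstrap a two-sided p-value for the
#'   difference between the raw and outlier-corrected estimates.
#' @return an object of class `mr_presso`: `rss_obs`, `global_pvalue`,
#'   `per_snp` (data frame with residuals, p-values and outlier flags),
#'   `outlier_rsids`, `raw` and `corrected` `mr_estimate`s (`corrected`
#'   is `NULL` when nothing is flagged), `distortion_pvalue`.
#' @examples
#' mr_presso(mr_fixture("calcium"), n_sim = 200, seed = 7)
#' @export
mr_presso <- function(data, n_sim = 1000, seed, outlier_alpha = 0.05,
                      distortion = FALSE) {
  stopifnot(inherits(data, "mr_dataset"))
  k <- n_snp(data)
  if (k < 4L)
    stop("mr_presso: need at least 4 SNPs, have ", k, call. = FALSE)
  if (n_sim < 100L)
    stop("mr_presso: n_sim must be at least 100", call. = FALSE)
  if (missing(seed)) stop("mr_presso: `seed` is required", call. = FALSE)
  s <- data$snps
  w_out <- 1 / s$se_outcome^2

  # leave-one-out fixed-effect IVW slopes, vectorized via sufficient sums
  loo_beta <- function(be, bo) {
    wr <- (be^2 / s$se_outcome^2)
    r <- bo / be
    (sum(wr * r) - wr * r) / (sum(wr) - wr)
  }
  b_loo <- loo_beta(s$beta_exposure, s$beta_outcome)
  resid_obs <- s$beta_outcome - b_loo * s$beta_exposure
  rss_obs <- sum(w_out * resid_obs^2)

  rw <- ratio_weights(data)
  b_full <- sum(rw$w * rw$r) / sum(rw$w)
  sim <- with_seed(seed, {
    BE <- matrix(stats::rnorm(k * n_sim, s$beta_exposure, s$se_exposure),
                 nrow = k)
    BO <- matrix(stats::rnorm(k * n_sim, b_full * s$beta_exposure,
                              s$se_outcome), nrow = k)
    list(BE = BE, BO = BO)
  })
  WR <- sim$BE^2 / s$se_outcome^2
  R <- sim$BO / sim$BE
  sum_w <- colSums(WR)
  sum_wr <- colSums(WR * R)
  B_loo <- sweep(-WR * R, 2, sum_wr, "+") / sweep(-WR, 2, sum_w, "+")
  RES <- sim$BO - B_loo * sim$BE
  RSS_sim <- colSums(w_out * RES^2)
  res2_obs <- w_out * resid_obs^2
  res2_sim <- w_out * RES^2

  global_pvalue <- (1 + sum(RSS_sim >= rss_obs)) / (n_sim + 1)
  per_p <- (1 + rowSums(res2_sim >= res2_obs)) / (n_sim + 1)
  flagged <- per_p < outlier_alpha / k
  per_snp <- data.frame(rsid = s$rsid, residual = resid_obs,
                        pvalue = per_p, outlier = flagged,
                        stringsAsFactors = FALSE)

  raw <- mr_ivw(data)
  corrected <- NULL
  if (any(flagged)) {
    if (!any(!flagged)) {
      warning("mr_presso: every SNP was flagged as an outlier; ",
              "no corrected estimate is possible", call. = FALSE)
    } else {
      # a single surviving SNP degrades to its Wald ratio via mr_ivw
      corrected <- mr_ivw(mr_dataset(s[!flagged, , drop = FALSE],
                                     data$exposure_name, data$outcome_name))
    }
  }

  distortion_pvalue <- NULL
  if (distortion && any(flagged)) {
    d_obs <- raw$beta - corrected$beta
    d_sim <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(b) {
        be <- stats::rnorm(k, s$beta_exposure, s$se_exposure)
        bo <- stats::rnorm(k, corrected$beta * s$beta_exposure,
                           s$se_outcome)
        wr <- be^2 / s$se_outcome^2
        r <- bo / be
        all_b <- sum(wr * r) / sum(wr)
        keep_b <- sum((wr * r)[!flagged]) / sum(wr[!flagged])
        all_b - keep_b
      }, numeric(1))
    })
    distortion_pvalue <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }

  structure(list(rss_obs = rss_obs, global_pvalue = global_pvalue,
                 per_snp = per_snp,
                 outlier_rsids = s$rsid[flagged],
                 raw = raw, corrected = corrected,
                 distortion_pvalue = distortion_pvalue,
                 n_sim = n_sim, seed = seed,
                 outlier_alpha = outlier_alpha),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.4f, P = %.3g (%d simulations)\n",
              x$rss_obs, x$global_pvalue, x$n_sim))
  if (length(x$outlier_rsids)) {
    cat("  outliers:", paste(x$outlier_rsids, collapse = ", "), "\n")
    cat(sprintf("  outlier-corrected OR %.3f (95%% CI %.3f-%.3f)\n",
                x$corrected$or, x$corrected$ci_low, x$corrected$ci_high))
  } else cat("  no outliers flagged\n")
  invisible(x)
}
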