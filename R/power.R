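#' Statistical power of a binary-outcome Mendelian randomization analysis
#'
#' Non-centrality-parameter power calculation for a two-sample MR study of
#' a binary outcome (the routine popularized by the mRnd online
#' calculator). With case fraction `K = n_cases / n_total` and
#' alternative-hypothesis odds ratio `OR` per SD of exposure, the attenuated
#' effect on the risk-difference scale is
#' `b = K * (OR / (1 + K * (OR - 1)) - 1)`, its variance
#' `v = (K * (1 - K) - b^2) / (n_total * r2)`, and the test statistic is
#' non-central chi-square with 1 df and `ncp = b^2 / v`; power is the
#' probability that it exceeds the central `1 - alpha` quantile.
#'
#' @param n_total total sample size of the outcome study.
#' @param n_cases number of cases (0 < n_cases < n_total).
#' @param r2 fraction of exposure variance explained by the instruments,
#'   in (0, 1).
#' @param alpha two-sided significance level.
#' @param or_alt alternative-hypothesis odds ratio per SD of exposure (> 0).
#' @return a list of class `mr_power`: `power` and `ncp`.
#' @examples
#' mr_power_binary(15666, 3968, r2 = 0.0046, or_alt = 1.88)
#' @export
mr_power_binary <- function(n_total, n_cases, r2, alpha = 0.05, or_alt) {
  if (!(n_cases > 0 && n_cases < n_total))
    stop("mr_power_binary: need 0 < n_cases < n_total", call. = FALSE)
  if (!(r2 > 0 && r2 < 1))
    stop("mr_power_binary: r2 must lie in (0, 1)", call. = FALSE)
  if (!(alpha > 0 && alpha < 1))
    stop("mr_power_binary: alpha must lie in (0, 1)", call. = FALSE)
  if (!(or_alt > 0))
    stop("mr_power_binary: or_alt must be > 0", call. = FALSE)
  K <- n_cases / n_total
  b <- K * (or_alt / (1 + K * (or_alt - 1)) - 1)
  v <- (K * (1 - K) - b^2) / (n_total * r2)
  if (v <= 0)
    stop(sprintf(paste0(
      "mr_power_binary: degenerate regime: the attenuated effect b = %.4f ",
      "exceeds sqrt(K(1-K)) = %.4f in magnitude, so the variance term is ",
      "non-positive; the normal approximation breaks down for this ",
      "case-fraction/odds-ratio combination"), b, sqrt(K * (1 - K))),
      call. = FALSE)
  ncp <- b^2 / v
  power <- stats::pchisq(stats::qchisq(1 - alpha, df = 1), df = 1,
                         ncp = ncp, lower.tail = FALSE)
  structure(list(power = power, ncp = ncp), class = "mr_power")
}

#' @export
print.mr_power <- function(x, ...) {
  cat(sprintf("MR binary-outcome power: %.3f (NCP %.3f)\n", x$power, x$ncp))
  invisible(x)
}

#' Minimum detectable odds ratio at a target power
#'
#' Inverts [mr_power_binary()] over the odds ratio by bisection. For
#' risk-increasing effects the bracket is `[1 + 1e-6, or_max]`, where
#' `or_max` is the smaller of 50 and the largest odds ratio at which the
#' power formula's variance term stays positive; power is strictly
#' increasing in the odds ratio on this bracket. `direction = "protective"`
#' mirrors the search below 1.
#'
#' @inheritParams mr_power_binary
#' @param target_power desired power, in (`alpha`, 1).
#' @param direction `"risk"` (OR > 1, default) or `"protective"` (OR < 1).
#' @param tol absolute tolerance on the odds ratio.
#' @return the detectable odds ratio (a single number).
#' @examples
#' mr_detectable_or(15666, 3968, r2 = 0.0046)  # ~1.88
#' @export
mr_detectable_or <- function(n_total, n_cases, r2, alpha = 0.05,
                             target_power = 0.80,
                             direction = c("risk", "protective"),
                             tol = 1e-6) {
  direction <- match.arg(direction)
  if (!(target_power > alpha && target_power < 1))
    stop("mr_detectable_or: target_power must lie in (alpha, 1)",
         call. = FALSE)
  K <- n_cases / n_total
  # largest |b| with positive variance is sqrt(K(1-K)); map back to OR
  bstar <- sqrt(K * (1 - K)) * (1 - 1e-9)
  x <- bstar / (1 - bstar)          # K * (OR - 1) at the boundary
  or_max <- min(50, 1 + x / K)
  pw <- function(or) mr_power_binary(n_total, n_cases, r2, alpha,
                                     or_alt = or)$power
  lo <- 1 + 1e-6
  hi <- or_max
  if (direction == "protective") {
    # mirrored bracket below 1; power increases as OR decreases
    lo <- 1 / or_max
    hi <- 1 - 1e-6
    f <- function(or) pw(or) - target_power
    if (f(lo) < 0 || f(hi) > 0)
      stop(sprintf(paste0("mr_detectable_or: target power %.3f outside the ",
                          "attainable range [%.4f, %.4f] on (%g, %g)"),
                   target_power, pw(hi), pw(lo), 1 / or_max, 1),
           call. = FALSE)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) >= 0) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    return((lo + hi) / 2)
  }
  f <- function(or) pw(or) - target_power
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf(paste0("mr_detectable_or: target power %.3f outside the ",
                        "attainable range [%.4f, %.4f] on (1, %.3f)"),
                 target_power, pw(lo), pw(hi), or_max), call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
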