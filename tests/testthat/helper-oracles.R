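# Independent reference implementations used to cross-check the package's
# estimators. Deliberately written in a different style (explicit loops,
# textbook formulas) from the code under test.

# classic fixed-effect meta-analysis of per-SNP Wald ratios: each ratio
# r_i = bo/be with delta-method variance (so/|be|)^2, pooled by 1/var
oracle_meta_ivw <- function(be, bo, so) {
  est <- numeric(length(be))
  var <- numeric(length(be))
  for (i in seq_along(be)) {
    est[i] <- bo[i] / be[i]
    var[i] <- (so[i] / abs(be[i]))^2
  }
  inv <- 1 / var
  list(beta = sum(est * inv) / sum(inv), se = sqrt(1 / sum(inv)))
}

# weighted median by explicit bracket search over cumulative midpoints
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  p <- w[o] / sum(w)
  k <- length(r)
  s <- numeric(k)
  acc <- 0
  for (i in seq_len(k)) {
    s[i] <- acc + p[i] / 2
    acc <- acc + p[i]
  }
  if (s[1] >= 0.5) return(r[1])
  if (s[k] <= 0.5) return(r[k])
  for (i in seq_len(k - 1)) {
    if (s[i] <= 0.5 && 0.5 <= s[i + 1]) {
      frac <- (0.5 - s[i]) / (s[i + 1] - s[i])
      return(r[i] + frac * (r[i + 1] - r[i]))
    }
  }
  stop("unreachable")
}

# weighted regression with intercept from the textbook 2x2 normal equations
oracle_egger <- function(be, bo, so) {
  w <- 1 / so^2
  sw <- sum(w); swx <- sum(w * be); swy <- sum(w * bo)
  swxx <- sum(w * be^2); swxy <- sum(w * be * bo)
  det <- sw * swxx - swx^2
  intercept <- (swxx * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  rss <- sum(w * (bo - intercept - slope * be)^2)
  # unscaled coefficient variances from the inverse normal-equations matrix
  var_int <- swxx / det
  var_slo <- sw / det
  list(intercept = intercept, slope = slope, rss_w = rss,
       se_intercept = sqrt(var_int), se_slope = sqrt(var_slo))
}

# random small harmonized dataset for property loops
random_dataset <- function(k, seed) {
  set.seed(seed)
  mr_dataset(data.frame(
    rsid = sprintf("rs%03d", seq_len(k)),
    effect_allele = "A",
    beta_exposure = runif(k, 0.01, 0.1) * sample(c(-1, 1), k, replace = TRUE),
    se_exposure = runif(k, 0.001, 0.005),
    beta_outcome = rnorm(k, 0, 0.05),
    se_outcome = runif(k, 0.02, 0.05)),
    exposure_name = "x", outcome_name = "y")
}

fixture_quiet <- function(name) suppressMessages(mr_fixture(name))
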