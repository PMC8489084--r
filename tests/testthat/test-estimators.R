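test_that("Wald ratio is the delta-method division of the paired effects", {
  d <- mr_dataset(data.frame(rsid = "rs1", beta_exposure = 1,
                             se_exposure = 0.01, beta_outcome = 0.07,
                             se_outcome = 0.03))
  est <- mr_wald_ratio(d)
  expect_equal(est$beta, 0.07)   # unit exposure effect: identity scaling
  expect_equal(est$se, 0.03)

  d$snps$beta_outcome <- 0
  expect_equal(mr_wald_ratio(d)$beta, 0)

  d25 <- mr_fixture("25OHD")
  est <- mr_wald_ratio(d25, "rs3755967")
  expect_equal(est$beta, 0.032 / 0.089, tolerance = 1e-12)
  expect_equal(est$se, 0.029 / 0.089, tolerance = 1e-12)

  d$snps$beta_exposure <- 0
  expect_error(mr_wald_ratio(d), "rs1")
})

test_that("IVW equals the inverse-variance meta-analysis of Wald ratios", {
  for (nm in c("25OHD", "calcium", "PTH")) {
    d <- mr_fixture(nm)
    s <- d$snps
    oracle <- oracle_meta_ivw(s$beta_exposure, s$beta_outcome, s$se_outcome)
    fit <- mr_ivw(d, mode = "fixed")
    expect_equal(fit$beta, oracle$beta, tolerance = 1e-12)
    expect_equal(fit$se, oracle$se, tolerance = 1e-12)
    expect_equal(mr_ivw(d, mode = "multiplicative_random")$beta,
                 oracle$beta, tolerance = 1e-12)
  }
  for (seed in 1:20) {
    d <- random_dataset(sample(2:10, 1), seed)
    s <- d$snps
    oracle <- oracle_meta_ivw(s$beta_exposure, s$beta_outcome, s$se_outcome)
    expect_equal(mr_ivw(d, "fixed")$beta, oracle$beta, tolerance = 1e-10)
    expect_equal(mr_ivw(d, "fixed")$se, oracle$se, tolerance = 1e-10)
  }
})

test_that("IVW invariances and the random-effects SE floor hold", {
  d <- mr_fixture("calcium")
  base <- mr_ivw(d)
  # permutation invariance
  perm <- mr_dataset(d$snps[sample(nrow(d$snps)), ],
                     d$exposure_name, d$outcome_name)
  expect_equal(mr_ivw(perm)$beta, base$beta, tolerance = 1e-12)
  # joint sign flip of one record leaves the estimate unchanged
  s <- d$snps
  s$beta_exposure[3] <- -s$beta_exposure[3]
  s$beta_outcome[3] <- -s$beta_outcome[3]
  expect_equal(mr_ivw(mr_dataset(s))$beta, base$beta, tolerance = 1e-12)

  # mre SE is never below the fixed SE; equal exactly when Q <= k-1
  for (seed in 1:10) {
    d <- random_dataset(6, seed + 100)
    fe <- mr_ivw(d, "fixed"); re <- mr_ivw(d, "multiplicative_random")
    expect_gte(re$se, fe$se)
    q <- mr_cochran_q(d)$q
    if (q <= n_snp(d) - 1) expect_equal(re$se, fe$se)
    else expect_gt(re$se, fe$se)
  }

  # single-record dataset degrades to the Wald ratio in both modes
  d1 <- mr_dataset(mr_fixture("25OHD")$snps[1, ])
  w <- mr_wald_ratio(d1)
  expect_equal(mr_ivw(d1, "fixed")$beta, w$beta)
  expect_equal(mr_ivw(d1, "multiplicative_random")$se, w$se)
})

test_that("weighted median interpolates the weight-ordered ratios", {
  # all ratios equal: estimate is that common value whatever the weights
  d <- mr_dataset(data.frame(rsid = paste0("rs", 1:4),
                             beta_exposure = c(0.1, 0.2, 0.05, 0.08),
                             se_exposure = 0.01,
                             beta_outcome = 0.3 * c(0.1, 0.2, 0.05, 0.08),
                             se_outcome = c(0.01, 0.03, 0.02, 0.05)))
  expect_equal(mr_weighted_median(d, n_boot = 10, seed = 1)$beta, 0.3,
               tolerance = 1e-12)

  # equal weights, ratios {1, 2, 9}: cumulative midpoint of the second
  # ratio sits exactly at 0.5, so the estimate is 2
  d <- mr_dataset(data.frame(rsid = paste0("rs", 1:3), beta_exposure = 0.1,
                             se_exposure = 0.01,
                             beta_outcome = 0.1 * c(1, 2, 9),
                             se_outcome = 0.02))
  expect_equal(mr_weighted_median(d, n_boot = 10, seed = 1)$beta, 2,
               tolerance = 1e-12)

  # matches the independently coded oracle exactly, and stays in range
  for (seed in 1:20) {
    d <- random_dataset(sample(3:10, 1), seed + 200)
    s <- d$snps
    r <- s$beta_outcome / s$beta_exposure
    w <- s$beta_exposure^2 / s$se_outcome^2
    est <- mr_weighted_median(d, n_boot = 2, seed = 1)$beta
    expect_equal(est, oracle_weighted_median(r, w), tolerance = 1e-8)
    expect_gte(est, min(r))
    expect_lte(est, max(r))
  }

  # nearly all weight on one SNP: estimate equals that SNP's ratio
  s <- random_dataset(5, 99)$snps
  s$se_outcome <- c(1e-6, 1, 1, 1, 1)
  d <- mr_dataset(s)
  expect_equal(mr_weighted_median(d, n_boot = 2, seed = 1)$beta,
               s$beta_outcome[1] / s$beta_exposure[1], tolerance = 1e-8)

  expect_error(mr_weighted_median(random_dataset(2, 1), seed = 1),
               "at least 3")
  expect_error(mr_weighted_median(random_dataset(5, 1), n_boot = 1,
                                  seed = 1), "n_boot")
})

test_that("weighted-median bootstrap is seed-deterministic with plausible SE", {
  d <- mr_fixture("25OHD")
  a <- mr_weighted_median(d, n_boot = 500, seed = 42)
  b <- mr_weighted_median(d, n_boot = 500, seed = 42)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(d, n_boot = 500, seed = 43)
  expect_false(identical(a$se, c$se))
  # bootstrap SE should be commensurate with the IVW SE on these data
  expect_gt(a$se, 0.1)
  expect_lt(a$se, 1)
})

test_that("Egger regression matches the normal-equations oracle", {
  # noiseless line: intercept and slope recovered to numerical precision
  be <- c(0.02, 0.04, 0.06, 0.09)
  d <- mr_dataset(data.frame(rsid = paste0("rs", 1:4), beta_exposure = be,
                             se_exposure = 0.003,
                             beta_outcome = 0.01 + 0.5 * be,
                             se_outcome = c(0.02, 0.03, 0.025, 0.04)))
  fit <- mr_egger(d)
  expect_equal(fit$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$intercept$estimate, 0.01, tolerance = 1e-10)

  for (seed in 1:20) {
    d <- random_dataset(sample(3:10, 1), seed + 300)
    s <- d$snps
    o <- oracle_egger(s$beta_exposure, s$beta_outcome, s$se_outcome)
    fit <- mr_egger(d)
    expect_equal(fit$slope$beta, o$slope, tolerance = 1e-8)
    expect_equal(fit$intercept$estimate, o$intercept, tolerance = 1e-8)
    infl <- max(1, sqrt(o$rss_w / (n_snp(d) - 2)))
    expect_equal(fit$slope$se, o$se_slope * infl, tolerance = 1e-8)
    expect_equal(fit$intercept$se, o$se_intercept * infl, tolerance = 1e-8)
  }

  # with the intercept pinned at zero the fit reproduces IVW exactly
  for (seed in 1:5) {
    d <- random_dataset(6, seed + 400)
    through_origin <- ivmr:::egger_wls(d, intercept = FALSE)
    expect_equal(unname(through_origin$coef), mr_ivw(d)$beta,
                 tolerance = 1e-10)
  }

  expect_error(mr_egger(random_dataset(2, 1)), "at least 3")
  s <- random_dataset(4, 1)$snps
  s$beta_exposure <- 0.05
  expect_error(mr_egger(mr_dataset(s)), "collinear")
})

test_that("Egger intercept test on the bundled data agrees with the published analysis", {
  # printed intercept p-values: 0.243, 0.997, 0.832; agreement is limited
  # by the 3-decimal rounding of the published inputs
  expect_equal(mr_egger(mr_fixture("25OHD"))$intercept$pvalue, 0.243,
               tolerance = 0.05)
  expect_equal(mr_egger(mr_fixture("calcium"))$intercept$pvalue, 0.997,
               tolerance = 0.05)
  expect_equal(mr_egger(mr_fixture("PTH"))$intercept$pvalue, 0.832,
               tolerance = 0.05)
})
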