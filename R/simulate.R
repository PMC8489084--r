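#' Configuration for simulated two-sample summary statistics
#'
#' Defines the ground truth for a simulated two-sample MR study: fixed
#' per-SNP instrument effects on the exposure, a causal effect on the
#' outcome, optional balanced or directional pleiotropy, and optional
#' planted outliers. Instrument effects, effect-allele frequencies and
#' alleles are drawn once, here, from `seed`, so that repeated calls to
#' [mr_simulate_pair()] with different seeds vary only the sampling noise —
#' the standard two-sample asymptotic setup in which instruments are fixed.
#'
#' @param n_snp number of instruments.
#' @param true_beta causal effect of the exposure on the outcome (log-odds
#'   per SD of exposure).
#' @param instrument_effects either an explicit vector of length `n_snp`,
#'   or a range `c(lo, hi)` to draw once from the uniform distribution.
#' @param se_exposure,se_outcome per-SNP standard errors; scalar
#'   (recycled) or vectors of length `n_snp`.
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero direct effects) or
#'   `"directional"` (mean `pleiotropy_mean`).
#' @param pleiotropy_sd standard deviation of per-SNP direct effects.
#' @param pleiotropy_mean mean direct effect (directional mode only).
#' @param n_outliers number of planted outlier SNPs (the first
#'   `n_outliers` variants).
#' @param outlier_shift additive log-odds shift applied to outliers' true
#'   outcome effects.
#' @param seed integer seed used for the once-per-config draws and as the
#'   default noise seed of [mr_simulate_pair()].
#' @return a list of class `mr_sim_config`.
#' @export
mr_sim_config <- function(n_snp, true_beta, instrument_effects = c(0.02, 0.1),
                          se_exposure = 0.003, se_outcome = 0.03,
                          pleiotropy = c("none", "balanced", "directional"),
                          pleiotropy_sd = 0, pleiotropy_mean = 0,
                          n_outliers = 0, outlier_shift = 0, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  if (n_snp < 1L) stop("mr_sim_config: n_snp must be >= 1", call. = FALSE)
  if (n_outliers >= n_snp && n_outliers > 0)
    stop("mr_sim_config: n_outliers must be < n_snp", call. = FALSE)
  if (pleiotropy_sd < 0)
    stop("mr_sim_config: pleiotropy_sd must be >= 0", call. = FALSE)
  se_exposure <- rep_len(se_exposure, n_snp)
  se_outcome <- rep_len(se_outcome, n_snp)
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop("mr_sim_config: standard errors must be > 0", call. = FALSE)

  drawn <- with_seed(seed, {
    # a vector of length n_snp is taken as the explicit effects; otherwise a
    # length-2 vector is a uniform range drawn from once (with n_snp = 2,
    # explicit interpretation wins)
    gamma <- if (length(instrument_effects) == n_snp)
      instrument_effects
    else if (length(instrument_effects) == 2L)
      stats::runif(n_snp, instrument_effects[1], instrument_effects[2])
    else stop("mr_sim_config: instrument_effects must be length n_snp or ",
              "a range c(lo, hi)", call. = FALSE)
    list(gamma = gamma, eaf = stats::runif(n_snp, 0.1, 0.9))
  })
  structure(list(
    n_snp = as.integer(n_snp), true_beta = true_beta,
    instrument_effects = drawn$gamma, eaf = drawn$eaf,
    se_exposure = se_exposure, se_outcome = se_outcome,
    pleiotropy = pleiotropy, pleiotropy_sd = pleiotropy_sd,
    pleiotropy_mean = pleiotropy_mean,
    n_outliers = as.integer(n_outliers), outlier_shift = outlier_shift,
    seed = as.integer(seed)), class = "mr_sim_config")
}

#' Simulation configuration matched to a bundled instrument set
#'
#' Builds an [mr_sim_config()] whose instrument count, instrument effect
#' sizes and exposure/outcome standard errors equal those of one of the
#' bundled instrument sets (see [mr_fixture()]), so simulations probe the
#' estimators at exactly the precision regime of the published data. The
#' causal effect and pleiotropy settings remain free.
#'
#' @param exposure_name one of `"25OHD"`, `"calcium"`, `"PTH"`.
#' @param true_beta causal effect used in simulation (default 0).
#' @param ... further arguments passed to [mr_sim_config()]
#'   (`pleiotropy`, `n_outliers`, `seed`, ...).
#' @return an `mr_sim_config`.
#' @examples
#' cfg <- mr_sim_config_matched("25OHD")
#' cfg$instrument_effects  # 0.089 0.036 0.031 0.026 0.017 0.017
#' @export
mr_sim_config_matched <- function(exposure_name, true_beta = 0, ...) {
  d <- mr_fixture(exposure_name)
  s <- d$snps
  mr_sim_config(n_snp = nrow(s), true_beta = true_beta,
                instrument_effects = s$beta_exposure,
                se_exposure = s$se_exposure, se_outcome = s$se_outcome,
                ...)
}

#' Read a simulation configuration from a key-value text file
#'
#' The file holds one `key = value` pair per line (`#` comments and blank
#' lines ignored). Keys are the arguments of [mr_sim_config()]; list-valued
#' fields (`instrument_effects`, `se_exposure`, `se_outcome`) may be
#' comma-separated. Example:
#'
#' ```
#' n_snp = 6
#' true_beta = 0.2
#' instrument_effects = 0.089, 0.036, 0.031, 0.026, 0.017, 0.017
#' se_outcome = 0.03
#' pleiotropy = balanced
#' pleiotropy_sd = 0.02
#' seed = 7
#' ```
#'
#' @param path file path.
#' @return an [mr_sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    stop("read_sim_config: no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("read_sim_config: cannot parse line: ", lines[bad][1],
         call. = FALSE)
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- vapply(kv, `[[`, character(1), 3L)
  known <- names(formals(mr_sim_config))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("read_sim_config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  args <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "pleiotropy") return(vals[i])
    x <- suppressWarnings(as.numeric(trimws(strsplit(vals[i], ",")[[1]])))
    if (anyNA(x))
      stop("read_sim_config: non-numeric value for ", keys[i],
           call. = FALSE)
    x
  })
  names(args) <- keys
  do.call(mr_sim_config, args)
}

#' Simulate a pair of exposure and outcome summary-statistic tables
#'
#' For SNP i with fixed instrument effect `gamma_i` (from the config), the
#' observed exposure beta is drawn `N(gamma_i, se_exp_i)`; the true outcome
#' effect is `Gamma_i = true_beta * gamma_i + alpha_i + outlier shift`,
#' with direct effect `alpha_i` zero, `N(0, pleiotropy_sd^2)` (balanced) or
#' `N(pleiotropy_mean, pleiotropy_sd^2)` (directional); the observed
#' outcome beta is drawn `N(Gamma_i, se_out_i)`. P-values come from the
#' simulated z-scores. Alleles alternate A/G (never palindromic) and need
#' no harmonization work.
#'
#' @param config an [mr_sim_config()].
#' @param seed noise seed; defaults to `config$seed`. Vary it across
#'   replicates to keep instruments fixed while redrawing sampling noise.
#' @return a list of class `mr_sim_pair`: `exposure` and `outcome`
#'   summary-statistic data frames, `truth` (per-SNP true effects, direct
#'   effects and outlier indices), and `dataset`, the harmonized
#'   [mr_dataset()] ready for the estimators.
#' @examples
#' pair <- mr_simulate_pair(mr_sim_config(6, true_beta = 0.2, seed = 3))
#' mr_ivw(pair$dataset)
#' @export
mr_simulate_pair <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "mr_sim_config"))
  k <- config$n_snp
  gamma <- config$instrument_effects
  alpha_shift <- with_seed(seed, {
    alpha <- switch(config$pleiotropy,
      none = rep(0, k),
      balanced = stats::rnorm(k, 0, config$pleiotropy_sd),
      directional = stats::rnorm(k, config$pleiotropy_mean,
                                 config$pleiotropy_sd))
    outlier_idx <- seq_len(config$n_outliers)
    Gamma <- config$true_beta * gamma + alpha
    Gamma[outlier_idx] <- Gamma[outlier_idx] + config$outlier_shift
    be <- stats::rnorm(k, gamma, config$se_exposure)
    bo <- stats::rnorm(k, Gamma, config$se_outcome)
    list(alpha = alpha, Gamma = Gamma, outlier_idx = outlier_idx,
         be = be, bo = bo)
  })
  rsid <- sprintf("rs%06d", seq_len(k))
  ea <- rep(c("A", "G"), length.out = k)
  oa <- rep(c("G", "A"), length.out = k)
  mk <- function(beta, se) data.frame(
    rsid = rsid, chrom = NA_character_, gene = NA_character_,
    effect_allele = ea, other_allele = oa, eaf = config$eaf,
    beta = beta, se = se, pvalue = two_sided_p(beta / se),
    stringsAsFactors = FALSE)
  exposure <- mk(alpha_shift$be, config$se_exposure)
  outcome <- mk(alpha_shift$bo, config$se_outcome)
  dataset <- mr_dataset(data.frame(
    rsid = rsid, effect_allele = ea, other_allele = oa,
    beta_exposure = alpha_shift$be, se_exposure = config$se_exposure,
    beta_outcome = alpha_shift$bo, se_outcome = config$se_outcome,
    eaf_exposure = config$eaf, stringsAsFactors = FALSE),
    exposure_name = "simulated exposure", outcome_name = "simulated outcome")
  structure(list(
    exposure = exposure, outcome = outcome,
    truth = list(true_beta = config$true_beta,
                 instrument_effects = gamma,
                 direct_effects = alpha_shift$alpha,
                 outcome_effects = alpha_shift$Gamma,
                 outlier_idx = alpha_shift$outlier_idx),
    dataset = dataset, seed = seed), class = "mr_sim_pair")
}
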