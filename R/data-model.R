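#' Validate a table of per-SNP association summary statistics
#'
#' A summary-statistics table holds one row per variant from a single GWAS,
#' with columns `rsid`, `chrom`, `gene`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se` and `pvalue`. `beta` is the per-effect-allele effect
#' (SD units for a quantitative exposure, log-odds for a binary outcome),
#' `se` its standard error, and `eaf` the effect-allele frequency (may be
#' `NA` when the source study does not report it).
#'
#' Hard invariants (errors): `se > 0`, `eaf` in \[0, 1\] when present,
#' `effect_allele != other_allele`, `pvalue` in (0, 1\]. A soft invariant
#' (warning only) checks that `pvalue` is consistent with the z-score
#' `|beta/se|` under the normal approximation; because published tables
#' round beta and se, the comparison is made on the z scale and only gross
#' disagreement (implied z differing by more than a factor of two and more
#' than one unit) is flagged.
#'
#' @param assoc data frame of summary statistics.
#' @param where label used in error messages (e.g. a file name).
#' @return `assoc`, invisibly, after validation.
#' @export
validate_associations <- function(assoc, where = "summary table") {
  req <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
  miss <- setdiff(req, names(assoc))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(assoc) == 0L) return(invisible(assoc))

  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(sprintf("%s: %s in row(s) %s (rsid %s)", where, what,
                   paste(i, collapse = ", "),
                   paste(assoc$rsid[i], collapse = ", ")), call. = FALSE)
  }
  bad(!is.finite(assoc$se) | assoc$se <= 0, "se must be > 0")
  bad(!is.na(assoc$eaf) & (assoc$eaf < 0 | assoc$eaf > 1),
      "eaf must lie in [0, 1]")
  bad(!is.finite(assoc$beta), "beta must be finite")
  bad(assoc$effect_allele == assoc$other_allele,
      "effect allele equals other allele")
  bad(!is.finite(assoc$pvalue) | assoc$pvalue <= 0 | assoc$pvalue > 1,
      "pvalue must lie in (0, 1]")

  # soft consistency: implied z from p versus |beta/se|
  z_bs <- abs(assoc$beta / assoc$se)
  z_p <- abs(stats::qnorm(log(assoc$pvalue) - log(2), log.p = TRUE))
  ratio <- pmax(z_bs, z_p) / pmax(pmin(z_bs, z_p), .Machine$double.eps)
  suspect <- is.finite(ratio) & ratio > 2 & abs(z_bs - z_p) > 1
  if (any(suspect))
    warning(sprintf(
      "%s: pvalue inconsistent with |beta/se| for %s",
      where, paste(assoc$rsid[suspect], collapse = ", ")), call. = FALSE)
  invisible(assoc)
}

#' Construct a harmonized exposure-outcome dataset
#'
#' The unit consumed by every estimator: per-SNP paired effects of the same
#' effect allele on the exposure (SD units) and on the outcome (log-odds).
#'
#' @param snps data frame with columns `rsid`, `effect_allele`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`, and
#'   optionally `other_allele`, `eaf_exposure`, `flipped`, `palindromic`.
#' @param exposure_name,outcome_name labels carried into all results.
#' @return an object of class `mr_dataset`.
#' @examples
#' d <- mr_dataset(data.frame(
#'   rsid = c("rs1", "rs2", "rs3"), effect_allele = "A",
#'   beta_exposure = c(0.1, 0.2, 0.15), se_exposure = 0.01,
#'   beta_outcome = c(0.05, 0.11, 0.07), se_outcome = 0.03),
#'   exposure_name = "trait", outcome_name = "disease")
#' print(d)
#' @export
mr_dataset <- function(snps, exposure_name = "exposure",
                       outcome_name = "outcome") {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("rsid", "beta_exposure", "se_exposure", "beta_outcome",
           "se_outcome")
  miss <- setdiff(req, names(snps))
  if (length(miss))
    stop("mr_dataset: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(snps) < 1L) stop("mr_dataset: need at least one SNP", call. = FALSE)
  if (anyDuplicated(snps$rsid))
    stop("mr_dataset: duplicated rsid(s): ",
         paste(unique(snps$rsid[duplicated(snps$rsid)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(snps$se_exposure) | snps$se_exposure <= 0))
    stop("mr_dataset: se_exposure must be > 0", call. = FALSE)
  if (any(!is.finite(snps$se_outcome) | snps$se_outcome <= 0))
    stop("mr_dataset: se_outcome must be > 0", call. = FALSE)
  if (is.null(snps$effect_allele)) snps$effect_allele <- NA_character_
  if (is.null(snps$flipped)) snps$flipped <- FALSE
  if (is.null(snps$palindromic)) snps$palindromic <- FALSE
  if (is.null(snps$eaf_exposure)) snps$eaf_exposure <- NA_real_
  rownames(snps) <- NULL
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 snps = snps),
            class = "mr_dataset")
}

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("Harmonized two-sample MR dataset: %s -> %s (%d SNPs)\n",
              x$exposure_name, x$outcome_name, nrow(x$snps)))
  print(x$snps[, intersect(c("rsid", "effect_allele", "beta_exposure",
                             "se_exposure", "beta_outcome", "se_outcome",
                             "flipped"), names(x$snps))],
        row.names = FALSE, ...)
  invisible(x)
}

#' Number of instruments in a harmonized dataset
#' @param x an `mr_dataset`.
#' @export
n_snp <- function(x) {
  stopifnot(inherits(x, "mr_dataset"))
  nrow(x$snps)
}

#' Drop one or more SNPs from a harmonized dataset
#' @param x an `mr_dataset`.
#' @param rsid variant identifier(s) to remove.
#' @return a smaller `mr_dataset`.
#' @export
drop_snp <- function(x, rsid) {
  stopifnot(inherits(x, "mr_dataset"))
  keep <- !(x$snps$rsid %in% rsid)
  if (all(keep)) warning("drop_snp: no matching rsid in dataset")
  if (!any(keep)) stop("drop_snp: would remove every SNP", call. = FALSE)
  mr_dataset(x$snps[keep, , drop = FALSE], x$exposure_name, x$outcome_name)
}

# per-SNP Wald ratios and first-order inverse-variance weights shared by
# IVW, weighted median and Cochran's Q:
#   r_i = beta_out / beta_exp,  w_i = beta_exp^2 / se_out^2  (= 1 / se(r_i)^2)
ratio_weights <- function(data) {
  s <- data$snps
  if (any(s$beta_exposure == 0))
    stop("zero exposure beta for SNP(s): ",
         paste(s$rsid[s$beta_exposure == 0], collapse = ", "), call. = FALSE)
  list(rsid = s$rsid,
       r = s$beta_outcome / s$beta_exposure,
       w = s$beta_exposure^2 / s$se_outcome^2)
}
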