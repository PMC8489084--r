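DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) {
  unname(DNA_COMPLEMENT[toupper(x)])
}

is_palindromic_pair <- function(ea, oa) {
  out <- complement_allele(ea) == oa
  out[is.na(out)] <- FALSE
  out
}

#' Harmonize exposure and outcome summary statistics onto a common allele
#'
#' Joins two association tables on `rsid` and expresses both effects per
#' copy of the exposure study's effect allele. For each shared variant:
#'
#' * identical effect/other alleles: kept as-is (`flipped = FALSE`);
#' * swapped alleles: outcome beta negated and outcome EAF complemented
#'   (`flipped = TRUE`);
#' * alleles matching only after strand complement (reported on the
#'   opposite strand): resolved, then the two rules above apply;
#' * palindromic variants (A/T or C/G) whose exposure EAF lies within
#'   `palindromic_eaf_window` of 0.5: dropped as strand-ambiguous;
#' * anything else irreconcilable: dropped.
#'
#' Dropped variants and strand resolutions are reported via `message()` and
#' recorded in the `"actions"` attribute of the result.
#'
#' @param exposure,outcome data frames of summary statistics
#'   (see [read_summary_table()]).
#' @param palindromic_eaf_window half-width of the ambiguity band around
#'   EAF 0.5 for palindromic variants; the default 0.08 drops variants with
#'   EAF in \[0.42, 0.58\].
#' @param reorient if `TRUE`, flip records so every exposure beta is
#'   non-negative (negating both betas and complementing the EAF). Off by
#'   default: the slope estimators are invariant to joint sign flips but
#'   the Egger intercept is not, so published orientations are preserved.
#' @param exposure_name,outcome_name labels for the resulting dataset.
#' @return an [mr_dataset()].
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08,
                      reorient = FALSE, exposure_name = "exposure",
                      outcome_name = "outcome") {
  validate_associations(exposure, "exposure table")
  validate_associations(outcome, "outcome table")
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L)
    stop("harmonize: no shared rsids between exposure and outcome",
         call. = FALSE)
  ex <- exposure[match(shared, exposure$rsid), , drop = FALSE]
  ou <- outcome[match(shared, outcome$rsid), , drop = FALSE]
  # preserve exposure row order
  ord <- order(match(shared, exposure$rsid))
  ex <- ex[ord, , drop = FALSE]; ou <- ou[ord, , drop = FALSE]

  k <- nrow(ex)
  keep <- rep(TRUE, k)
  flipped <- rep(FALSE, k)
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  palindromic <- is_palindromic_pair(ex$effect_allele, ex$other_allele)
  actions <- character(k)

  for (i in seq_len(k)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (palindromic[i]) {
      eaf_ref <- if (!is.na(ex$eaf[i])) ex$eaf[i] else ou$eaf[i]
      if (!is.na(eaf_ref) &&
          abs(eaf_ref - 0.5) <= palindromic_eaf_window) {
        keep[i] <- FALSE
        actions[i] <- "dropped: palindromic with ambiguous frequency"
        next
      }
    }
    if (identical(ea_y, ea_x) && identical(oa_y, oa_x)) {
      actions[i] <- "kept"
    } else if (identical(ea_y, oa_x) && identical(oa_y, ea_x)) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      flipped[i] <- TRUE
      actions[i] <- "allele swap"
    } else if (!palindromic[i] &&
               identical(complement_allele(ea_y), ea_x) &&
               identical(complement_allele(oa_y), oa_x)) {
      actions[i] <- "strand complement"
    } else if (!palindromic[i] &&
               identical(complement_allele(ea_y), oa_x) &&
               identical(complement_allele(oa_y), ea_x)) {
      beta_out[i] <- -beta_out[i]
      if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      flipped[i] <- TRUE
      actions[i] <- "strand complement + allele swap"
    } else {
      keep[i] <- FALSE
      actions[i] <- "dropped: irreconcilable alleles"
    }
  }
  log <- data.frame(rsid = ex$rsid, action = actions,
                    stringsAsFactors = FALSE)
  noteworthy <- log$action != "kept"
  if (any(noteworthy))
    message("harmonize: ", paste(sprintf("%s (%s)", log$rsid[noteworthy],
                                         log$action[noteworthy]),
                                 collapse = "; "))
  if (!any(keep))
    stop("harmonize: no variants left after harmonization", call. = FALSE)

  snps <- data.frame(
    rsid = ex$rsid[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    beta_outcome = beta_out[keep],
    se_outcome = ou$se[keep],
    eaf_exposure = ex$eaf[keep],
    flipped = flipped[keep],
    palindromic = palindromic[keep],
    stringsAsFactors = FALSE)

  if (reorient) {
    neg <- snps$beta_exposure < 0
    snps$beta_exposure[neg] <- -snps$beta_exposure[neg]
    snps$beta_outcome[neg] <- -snps$beta_outcome[neg]
    ea <- snps$effect_allele[neg]
    snps$effect_allele[neg] <- snps$other_allele[neg]
    snps$other_allele[neg] <- ea
    snps$eaf_exposure[neg] <- 1 - snps$eaf_exposure[neg]
  }

  out <- mr_dataset(snps, exposure_name, outcome_name)
  attr(out, "actions") <- log
  out
}

#' Export a harmonized dataset as tab-separated text
#'
#' @param data an [mr_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(data, path) {
  stopifnot(inherits(data, "mr_dataset"))
  out <- data$snps
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
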