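#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab-separated by default) with one row per
#' variant into the canonical summary-statistics layout. Arbitrary column
#' names are supported through `dialect`, a named character vector mapping
#' canonical names to the names used in the file, e.g.
#' `c(rsid = "SNP", beta = "Effect", se = "StdErr", pvalue = "P")`.
#'
#' Numeric fields accept decimal or scientific notation. P-values smaller
#' than the smallest representable double (e.g. `4.74E-343`) are clamped to
#' `.Machine$double.xmin` so that downstream strict-positivity invariants
#' hold; the printed order of magnitude below ~1e-308 is not representable
#' in double precision.
#'
#' @param path file path.
#' @param dialect named character vector remapping canonical column names
#'   (`rsid`, `chrom`, `gene`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`) to the file's column names. Unmapped canonical
#'   names are looked up as-is. `chrom`, `gene` and `eaf` are optional.
#' @param sep field separator, tab by default.
#' @return data frame of summary statistics, row order preserved, validated
#'   by [validate_associations()].
#' @export
read_summary_table <- function(path, dialect = NULL, sep = "\t") {
  if (!file.exists(path))
    stop("read_summary_table: no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  canonical <- c("rsid", "chrom", "gene", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue")
  optional <- c("chrom", "gene", "eaf")
  colmap <- stats::setNames(canonical, canonical)
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), canonical)
    if (length(unknown))
      stop("read_summary_table: dialect maps unknown field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    colmap[names(dialect)] <- dialect
  }
  get_col <- function(canon) {
    nm <- colmap[[canon]]
    if (!nm %in% names(raw)) {
      if (canon %in% optional) return(rep(NA_character_, nrow(raw)))
      stop(sprintf(
        "read_summary_table: column '%s' (for field '%s') not found in %s",
        nm, canon, path), call. = FALSE)
    }
    raw[[nm]]
  }
  parse_num <- function(x, field) {
    y <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(y) & !is.na(x) & x != "" & toupper(x) != "NA")
    if (length(bad))
      stop(sprintf(
        "read_summary_table: unparseable %s value '%s' at line %d of %s",
        field, x[bad[1]], bad[1] + 1L, path), call. = FALSE)
    # scientific-notation values below double range underflow to 0; keep the
    # strict-positivity invariant by clamping to the smallest positive double
    under <- which(y == 0 & grepl("^[^0]", trimws(x)) &
                     grepl("[eE]-", x))
    y[under] <- .Machine$double.xmin
    y
  }
  assoc <- data.frame(
    rsid = get_col("rsid"),
    chrom = get_col("chrom"),
    gene = get_col("gene"),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = parse_num(get_col("eaf"), "eaf"),
    beta = parse_num(get_col("beta"), "beta"),
    se = parse_num(get_col("se"), "se"),
    pvalue = parse_num(get_col("pvalue"), "pvalue"),
    stringsAsFactors = FALSE)
  validate_associations(assoc, where = path)
  assoc
}

#' Write a summary-statistics table
#'
#' Inverse of [read_summary_table()]: writes tab-separated text with the
#' canonical header. Numeric fields are written with 17 significant digits
#' so a read/write round trip reproduces every value exactly.
#'
#' @param assoc data frame of summary statistics.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(assoc, path) {
  out <- assoc
  for (col in c("eaf", "beta", "se", "pvalue"))
    if (col %in% names(out))
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           sprintf("%.17g", out[[col]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter instruments on association strength
#'
#' Retains variants whose exposure p-value is strictly below the
#' genome-wide significance threshold, enforcing the instrumental-variable
#' relevance assumption. Row order is preserved.
#'
#' @param assoc data frame of summary statistics.
#' @param threshold p-value threshold in (0, 1); default the conventional
#'   genome-wide level `5e-8`.
#' @return the retained subset of `assoc`.
#' @export
significance_filter <- function(assoc, threshold = 5e-8) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("significance_filter: threshold must lie in (0, 1]", call. = FALSE)
  out <- assoc[assoc$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a bundled instrument set
#'
#' The package ships the published instruments for three calcium-pathway
#' exposures of coronary artery disease in diabetes, as exposure/outcome
#' summary-statistic pairs: 6 SNPs for serum 25-hydroxyvitamin D
#' (`"25OHD"`), 7 for serum calcium (`"calcium"`), 5 for serum parathyroid
#' hormone (`"PTH"`). Values are stored exactly as published (3 decimals,
#' scientific-notation p-values). The exposure and outcome studies report
#' the same effect/other alleles, so harmonization leaves all effects
#' unchanged.
#'
#' @param exposure_name one of `"25OHD"`, `"calcium"`, `"PTH"`
#'   (case-insensitive).
#' @param harmonized if `TRUE` (default) return the harmonized
#'   [mr_dataset()]; if `FALSE`, a list with the raw `exposure` and
#'   `outcome` association tables.
#' @return an `mr_dataset`, or a list of two data frames.
#' @examples
#' d <- mr_fixture("25OHD")
#' n_snp(d)  # 6
#' @export
mr_fixture <- function(exposure_name, harmonized = TRUE) {
  key <- c("25ohd" = "25ohd", "calcium" = "calcium", "pth" = "pth",
           "ca" = "calcium")[tolower(exposure_name)]
  if (is.na(key))
    stop("mr_fixture: unknown exposure '", exposure_name,
         "'; valid names: 25OHD, calcium, PTH", call. = FALSE)
  label <- c("25ohd" = "S-25OHD", "calcium" = "S-Ca", "pth" = "S-PTH")[[key]]
  path <- function(side) system.file(
    "extdata", sprintf("%s_%s.tsv", key, side), package = "ivmr",
    mustWork = TRUE)
  exposure <- read_summary_table(path("exposure"))
  outcome <- read_summary_table(path("outcome"))
  if (!harmonized)
    return(list(exposure = exposure, outcome = outcome,
                exposure_name = label))
  harmonize(exposure, outcome, exposure_name = label,
            outcome_name = "CAD in diabetes")
}
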