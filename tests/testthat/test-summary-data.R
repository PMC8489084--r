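test_that("bundled instrument sets load with the published dimensions and values", {
  d25 <- mr_fixture("25OHD")
  dca <- mr_fixture("calcium")
  dpt <- mr_fixture("PTH")
  expect_equal(n_snp(d25), 6L)
  expect_equal(n_snp(dca), 7L)
  expect_equal(n_snp(dpt), 5L)

  r <- d25$snps[d25$snps$rsid == "rs3755967", ]
  expect_equal(r$beta_exposure, 0.089)
  expect_equal(r$se_exposure, 0.002)
  expect_equal(r$beta_outcome, 0.032)
  expect_equal(r$se_outcome, 0.029)

  r <- dca$snps[dca$snps$rsid == "rs780094", ]
  expect_equal(r$beta_outcome, 0.085)
  expect_equal(r$se_outcome, 0.028)

  r <- dpt$snps[dpt$snps$rsid == "rs6127099", ]
  expect_equal(r$beta_exposure, 0.070)
  expect_equal(r$beta_outcome, 0.021)

  # published tables are pre-harmonized: identical alleles, nothing flipped
  expect_false(any(d25$snps$flipped))
  expect_false(any(dca$snps$flipped))
  expect_false(any(dpt$snps$flipped))

  expect_error(mr_fixture("vitamink"), "valid names")
})

test_that("reader handles dialects, scientific notation, and malformed input", {
  raw <- mr_fixture("25OHD", harmonized = FALSE)
  expect_equal(raw$exposure$rsid[1], "rs3755967")
  expect_equal(raw$exposure$beta[1], 0.089)
  # 4.74E-343 underflows double range; clamped to smallest positive double
  expect_gt(raw$exposure$pvalue[1], 0)
  expect_lt(raw$exposure$pvalue[1], 1e-300)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tEffect\tStdErr\tP",
               "rs1\tA\tG\t0.05\t0.01\t1.2e-9"), tmp)
  dial <- c(rsid = "SNP", effect_allele = "EA", other_allele = "OA",
            beta = "Effect", se = "StdErr", pvalue = "P")
  got <- read_summary_table(tmp, dialect = dial)
  expect_equal(got$beta, 0.05)
  expect_equal(got$pvalue, 1.2e-9)

  # missing column named in the error
  expect_error(read_summary_table(tmp), "rsid")

  # header-only file gives an empty table
  writeLines("rsid\tchrom\tgene\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue",
             tmp)
  expect_equal(nrow(read_summary_table(tmp)), 0L)

  # unparseable numeric reported with its line number
  writeLines(c("rsid\teffect_allele\tother_allele\tbeta\tse\tpvalue",
               "rs1\tA\tG\t0.05\t0.01\t1e-9",
               "rs2\tA\tG\tbogus\t0.01\t1e-9"), tmp)
  expect_error(read_summary_table(tmp), "line 3")

  # se of zero violates a hard invariant, reported per row
  writeLines(c("rsid\teffect_allele\tother_allele\tbeta\tse\tpvalue",
               "rs1\tA\tG\t0.05\t0\t1e-9"), tmp)
  expect_error(read_summary_table(tmp), "se must be > 0")
})

test_that("p-value/z-score consistency is a warning, not an error", {
  assoc <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                      eaf = 0.5, beta = 1, se = 0.1, pvalue = 0.5)
  expect_warning(validate_associations(assoc), "inconsistent")
  # published rounding of tiny p-values must not warn
  raw <- mr_fixture("25OHD", harmonized = FALSE)
  expect_silent(validate_associations(raw$exposure))
})

test_that("write/read round trip preserves every numeric field exactly", {
  raw <- mr_fixture("calcium", harmonized = FALSE)$exposure
  raw$beta <- raw$beta + pi * 1e-9  # force full-precision values
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(raw, tmp)
  back <- read_summary_table(tmp)
  for (col in c("eaf", "beta", "se", "pvalue"))
    expect_identical(back[[col]], raw[[col]])
})

test_that("significance filter is strict, order-preserving and monotone", {
  all18 <- rbind(mr_fixture("25OHD", harmonized = FALSE)$exposure,
                 mr_fixture("calcium", harmonized = FALSE)$exposure,
                 mr_fixture("PTH", harmonized = FALSE)$exposure)
  kept <- significance_filter(all18)
  expect_equal(nrow(kept), 18L)            # max exposure p is 4.72e-9
  expect_equal(kept$rsid, all18$rsid)

  boundary <- data.frame(rsid = c("a", "b"), effect_allele = "A",
                         other_allele = "G", eaf = 0.5,
                         beta = c(0.1, 0.1), se = 0.01,
                         pvalue = c(5e-8, 4.9e-8))
  expect_equal(significance_filter(boundary)$rsid, "b")  # strict <

  expect_equal(nrow(significance_filter(all18[0, ])), 0L)
  expect_identical(significance_filter(all18, 1.0), all18)
  # monotone: smaller threshold keeps a subset
  for (thr in c(1e-10, 1e-30, 1e-80)) {
    sub <- significance_filter(all18, thr)
    expect_true(all(sub$rsid %in% kept$rsid))
    expect_true(all(sub$pvalue < thr))
  }
  expect_error(significance_filter(all18, 0), "threshold")
})

make_pair <- function(ea_y, oa_y, beta_y = 0.05, eaf_y = 0.3, eaf_x = 0.3,
                      ea_x = "A", oa_x = "G") {
  list(
    exposure = data.frame(rsid = "rs1", effect_allele = ea_x,
                          other_allele = oa_x, eaf = eaf_x, beta = 0.1,
                          se = 0.01, pvalue = 1e-10),
    outcome = data.frame(rsid = "rs1", effect_allele = ea_y,
                         other_allele = oa_y, eaf = eaf_y, beta = beta_y,
                         se = 0.02, pvalue = 0.01))
}

test_that("harmonization aligns, flips, strand-resolves and drops correctly", {
  # identical alleles: untouched
  p <- make_pair("A", "G")
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$snps$beta_outcome, 0.05)
  expect_false(h$snps$flipped)

  # swapped alleles: beta negated, eaf complemented
  p <- make_pair("G", "A")
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$snps$beta_outcome, -0.05)
  expect_true(h$snps$flipped)

  # the swap transform is an involution: swapping the already-swapped
  # outcome restores the original
  out2 <- p$outcome
  out2$effect_allele <- "A"; out2$other_allele <- "G"
  out2$beta <- -out2$beta; out2$eaf <- 1 - out2$eaf
  h2 <- harmonize(p$exposure, out2)
  expect_equal(h2$snps$beta_outcome, -0.05)

  # opposite-strand report: T/C complements to A/G
  p <- make_pair("T", "C")
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$snps$beta_outcome, 0.05)
  expect_false(h$snps$flipped)

  # opposite strand and swapped: C/T -> G/A -> swap
  p <- make_pair("C", "T")
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$snps$beta_outcome, -0.05)
  expect_true(h$snps$flipped)

  # palindromic with ambiguous frequency is dropped (and errors when it
  # was the only variant)
  p <- make_pair("A", "T", ea_x = "A", oa_x = "T", eaf_x = 0.50)
  expect_error(suppressMessages(harmonize(p$exposure, p$outcome)),
               "no variants left")
  # palindromic with informative frequency is kept
  p <- make_pair("A", "T", ea_x = "A", oa_x = "T", eaf_x = 0.18)
  h <- harmonize(p$exposure, p$outcome)
  expect_true(h$snps$palindromic)

  # irreconcilable alleles dropped with a logged reason
  p2 <- make_pair("A", "C")
  p2$exposure <- rbind(p2$exposure, make_pair("A", "G")$exposure)
  p2$exposure$rsid <- c("rs1", "rs2")
  p2$outcome <- rbind(p2$outcome, make_pair("A", "G")$outcome)
  p2$outcome$rsid <- c("rs1", "rs2")
  expect_message(h <- harmonize(p2$exposure, p2$outcome), "irreconcilable")
  expect_equal(h$snps$rsid, "rs2")
  expect_equal(attr(h, "actions")$action[1], "dropped: irreconcilable alleles")

  expect_error(harmonize(make_pair("A", "G")$exposure,
                         transform(make_pair("A", "G")$outcome,
                                   rsid = "rsX")),
               "no shared rsids")
})

test_that("harmonization is idempotent on already-harmonized data", {
  raw <- mr_fixture("PTH", harmonized = FALSE)
  h1 <- harmonize(raw$exposure, raw$outcome)
  # feed the harmonized records back through as an outcome table
  out_again <- data.frame(rsid = h1$snps$rsid,
                          effect_allele = h1$snps$effect_allele,
                          other_allele = h1$snps$other_allele,
                          eaf = NA_real_,
                          beta = h1$snps$beta_outcome,
                          se = h1$snps$se_outcome,
                          pvalue = 2 * pnorm(-abs(h1$snps$beta_outcome /
                                                    h1$snps$se_outcome)))
  h2 <- harmonize(raw$exposure, out_again)
  expect_equal(h2$snps$beta_outcome, h1$snps$beta_outcome)
  expect_equal(h2$snps$beta_exposure, h1$snps$beta_exposure)
  expect_false(any(h2$snps$flipped))
})

test_that("reorientation flips records to non-negative exposure effects", {
  ex <- data.frame(rsid = c("rs1", "rs2"), effect_allele = c("A", "A"),
                   other_allele = c("G", "G"), eaf = c(0.3, 0.6),
                   beta = c(-0.1, 0.2), se = 0.01)
  ex$pvalue <- 2 * pnorm(-abs(ex$beta / ex$se))
  ou <- ex; ou$beta <- c(0.05, -0.03); ou$se <- 0.02
  ou$pvalue <- 2 * pnorm(-abs(ou$beta / ou$se))
  h <- harmonize(ex, ou, reorient = TRUE)
  expect_true(all(h$snps$beta_exposure >= 0))
  expect_equal(h$snps$beta_outcome, c(-0.05, -0.03))
  expect_equal(h$snps$eaf_exposure, c(0.7, 0.6))
  # slope-estimator invariance under reorientation
  h0 <- harmonize(ex, ou, reorient = FALSE)
  expect_equal(mr_ivw(h)$beta, mr_ivw(h0)$beta)
})

test_that("dataset constructor enforces its invariants", {
  good <- data.frame(rsid = c("rs1", "rs2"), beta_exposure = 0.1,
                     se_exposure = 0.01, beta_outcome = 0.02,
                     se_outcome = 0.02)
  expect_s3_class(mr_dataset(good), "mr_dataset")
  expect_error(mr_dataset(good[0, ]), "at least one")
  dup <- good; dup$rsid <- "rs1"
  expect_error(mr_dataset(dup), "duplicated")
  bad <- good; bad$se_outcome <- c(0.02, 0)
  expect_error(mr_dataset(bad), "se_outcome")
  expect_equal(n_snp(drop_snp(mr_dataset(good), "rs1")), 1L)
})
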