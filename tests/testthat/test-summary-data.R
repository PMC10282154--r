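test_that("delimited summary files parse, clean and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t1000\ta\tg\t0.31\t0.10\t0.02\t5e-7\t10000",
    "rs2\t1\t2000\tC\tt\t0.22\t-0.05\t0.03\t0.04\t10000",
    "rs3\t2\t3000\tG\tA\t0.45\t0.02\t0.01\t0.2\t10000"
  ), path)
  ss <- read_summary_stats(path, trait_name = "tea", trait_type = "continuous")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 3L)
  # alleles upper-cased on ingest
  expect_equal(ss$effect_allele, c("A", "C", "G"))
  expect_equal(ss$other_allele, c("G", "T", "A"))
  expect_identical(attr(ss, "n_dropped"), 0L)

  # hand-parsed comparison for the full record
  expect_equal(ss$beta, c(0.10, -0.05, 0.02))
  expect_equal(ss$se, c(0.02, 0.03, 0.01))
  expect_equal(ss$pval, c(5e-7, 0.04, 0.2))

  # non-positive SE rows are dropped and counted
  writeLines(c(
    "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
    "rs1\t1\t1000\tA\tG\t0.3\t0.1\t0.02\t5e-7\t10000",
    "rs2\t1\t2000\tC\tT\t0.2\t0.1\t0\t0.04\t10000"
  ), path)
  ss2 <- read_summary_stats(path, trait_type = "continuous")
  expect_equal(nrow(ss2), 1L)
  expect_identical(attr(ss2, "n_dropped"), 1L)

  # a missing mandatory column is a format error
  writeLines(c("SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tN",
               "rs1\t1\t1000\tA\tG\t0.3\t0.1\t0.02\t10000"), path)
  expect_error(read_summary_stats(path, trait_type = "binary"), "mandatory")
})

test_that("custom column maps and csv files are honoured", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rsid,chr,bp,a1,a2,freq,b,stderr,pv,samples",
               "rs9,3,500,T,C,0.12,0.2,0.05,1e-4,5000"), path)
  ss <- read_summary_stats(path, trait_type = "binary", column_map = c(
    variant_id = "rsid", chrom = "chr", pos = "bp", effect_allele = "a1",
    other_allele = "a2", eaf = "freq", beta = "b", se = "stderr",
    pval = "pv", n = "samples"))
  expect_equal(ss$variant_id, "rs9")
  expect_equal(ss$beta, 0.2)
})

test_that("harmonization aligns, flips and complements as required", {
  ex <- make_stats(c("rs1", "rs2", "rs3", "rs4"),
                   beta = c(0.1, 0.1, 0.1, 0.1), se = rep(0.02, 4),
                   ea = c("A", "A", "A", "A"), oa = c("G", "G", "G", "G"),
                   eaf = 0.3, trait = "exposure")
  # rs1 identical, rs2 swapped, rs3 strand-complement, rs4 complement+swapped
  ou <- summary_stats(tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "1", pos = c(2e6, 4e6, 6e6, 8e6),
    effect_allele = c("A", "G", "T", "C"),
    other_allele  = c("G", "A", "C", "T"),
    eaf = c(0.3, 0.7, 0.3, 0.7),
    beta = c(0.2, 0.2, 0.2, 0.2), se = 0.05, pval = 0.001, n = 1e5
  ), "outcome", "binary")
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 4L)
  expect_equal(h$by[h$variant_id == "rs1"], 0.2)
  expect_equal(h$by[h$variant_id == "rs2"], -0.2)
  expect_equal(h$by[h$variant_id == "rs3"], 0.2)
  expect_equal(h$by[h$variant_id == "rs4"], -0.2)
})

test_that("palindromic variants are frequency-oriented or dropped", {
  pal_ex <- function(eaf) make_stats("rs1", 0.1, 0.02, ea = "A", oa = "T",
                                     eaf = eaf, trait = "exposure")
  pal_ou <- function(eaf, ea = "A", oa = "T") summary_stats(tibble::tibble(
    variant_id = "rs1", chrom = "1", pos = 2e6, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = 0.2, se = 0.05, pval = 0.001, n = 1e5
  ), "outcome", "binary")

  # both frequencies well below 0.5: same orientation
  h1 <- harmonize(pal_ex(0.2), pal_ou(0.25))
  expect_equal(h1$by, 0.2)
  # frequencies on opposite sides: sign flip
  h2 <- harmonize(pal_ex(0.2), pal_ou(0.8))
  expect_equal(h2$by, -0.2)
  # ambiguous frequency near 0.5: dropped with the documented reason
  h3 <- harmonize(pal_ex(0.5), pal_ou(0.2))
  expect_equal(nrow(h3), 0L)
  expect_equal(harmonization_drops(h3)$reason, "palindromic_ambiguous")
  # missing frequency: dropped too
  h4 <- harmonize(pal_ex(NA), pal_ou(0.2))
  expect_equal(harmonization_drops(h4)$reason, "palindromic_ambiguous")
  # window is configurable: eaf 0.45 is ambiguous at the default window
  # ([0.42, 0.58]) but usable with a narrower one
  h5 <- harmonize(pal_ex(0.45), pal_ou(0.45))
  expect_equal(nrow(h5), 0L)
  h6 <- harmonize(pal_ex(0.45), pal_ou(0.45), palindromic_eaf_window = 0.03)
  expect_equal(h6$by, 0.2)
})

test_that("harmonization bookkeeping: idempotence, sign symmetry, accounting", {
  set.seed(11)
  J <- 20
  ids <- sprintf("rs%02d", 1:J)
  ex <- make_stats(ids, rnorm(J, 0, 0.05), runif(J, 0.01, 0.03),
                   ea = sample(c("A", "C"), J, TRUE), oa = "G",
                   eaf = runif(J, 0.1, 0.4), trait = "exposure")
  ou_tbl <- tibble::tibble(
    variant_id = ids, chrom = "1", pos = seq_len(J) * 2e6,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf = ex$eaf, beta = rnorm(J, 0, 0.05), se = runif(J, 0.02, 0.05),
    pval = runif(J), n = 1e5
  )
  ou <- summary_stats(ou_tbl, "outcome", "binary")
  h <- harmonize(ex, ou)

  # idempotent: re-harmonizing the aligned pair changes no betas
  ou_aligned <- summary_stats(
    dplyr::mutate(ou_tbl, beta = h$by[match(variant_id, h$variant_id)]),
    "outcome", "binary")
  h2 <- harmonize(ex, ou_aligned)
  expect_equal(h2$by, h$by)
  expect_equal(h2$bx, h$bx)

  # sign symmetry: relabelling outcome alleles and negating betas is a no-op
  ou_flip <- summary_stats(dplyr::mutate(
    ou_tbl, effect_allele = ou_tbl$other_allele,
    other_allele = ou_tbl$effect_allele,
    beta = -beta, eaf = 1 - eaf), "outcome", "binary")
  h3 <- harmonize(ex, ou_flip)
  expect_equal(h3$by, h$by)
  expect_equal(h3$variant_id, h$variant_id)

  # retained + dropped = intersection
  expect_equal(nrow(h) + nrow(harmonization_drops(h)), J)

  # empty intersection errors with both trait names
  ou_other <- make_stats("zz9", 0.1, 0.05, trait = "outcome", type = "binary")
  expect_error(harmonize(ex, ou_other), "exposure.*outcome")
})
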