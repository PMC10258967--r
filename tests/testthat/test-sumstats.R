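test_that("read_sumstats converts odds ratios, fills z and p, enforces columns", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP CHR BP A1 A2 OR SE P N",
               "rs1 1 1000 A G 1.10 0.05 0.06 5000",
               "rs2 1 2000 C T 0.90 0.04 0.01 5000"), f)
  dia <- list(snp_id = "SNP", chrom = "CHR", pos = "BP",
              effect_allele = "A1", other_allele = "A2",
              or = "OR", se = "SE", p = "P", n = "N")
  ss <- read_sumstats(f, dia)
  expect_equal(ss$beta[1], log(1.10), tolerance = 1e-12)
  expect_equal(ss$beta[1], 0.09531, tolerance = 1e-4)
  expect_equal(ss$z, ss$beta / ss$se, tolerance = 1e-12)

  # z derived from beta/se when no Z column
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP CHR BP A1 A2 BETA SE",
               "rs1 1 1000 A G 0.1 0.05"), f2)
  dia2 <- list(snp_id = "SNP", chrom = "CHR", pos = "BP",
               effect_allele = "A1", other_allele = "A2",
               beta = "BETA", se = "SE")
  ss2 <- read_sumstats(f2, dia2)
  expect_equal(ss2$z, 2.0)
  expect_equal(ss2$p, two_sided_p(2.0))

  # missing SE column is a configuration error naming the column
  dia3 <- dia2; dia3$se <- "SE_MISSING"
  expect_error(read_sumstats(f2, dia3), "SE_MISSING")

  # unparseable numeric carries the line number
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP CHR BP A1 A2 BETA SE",
               "rs1 1 1000 A G 0.1 0.05",
               "rs2 1 oops A G 0.2 0.05"), f3)
  expect_error(read_sumstats(f3, dia2), "line 2")
})

test_that("sumstat_table validates identifiers and keeps z/beta/se coherent", {
  expect_error(mk_ss(c("rs1", "rs1"), c(0.1, 0.2), c(0.05, 0.05)), "unique")
  ss <- mk_ss(c("rs1", "rs2"), c(0.1, -0.2), c(0.05, 0.1))
  expect_true(all(abs(ss$z - ss$beta / ss$se) < 1e-6 * pmax(1, abs(ss$z))))
  expect_equal(ss$p, two_sided_p(ss$z), tolerance = 1e-6)
})

test_that("writing then reading a table reproduces numeric fields", {
  ss <- mk_ss(sprintf("rs%d", 1:20), rnorm(20, 0, 0.1), runif(20, 0.01, 0.1),
              maf = runif(20, 0.05, 0.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, f)
  back <- read_sumstats(f, std_dialect, sep = "\t")
  for (col in c("beta", "se", "z", "p", "n", "maf")) {
    expect_equal(back[[col]], ss[[col]], tolerance = 1e-12, label = col)
  }
})

test_that("qc_filter applies the ordered filters and is idempotent", {
  pan <- genotype_panel(
    matrix(rep(c(0, 1, 2, 1), 6), nrow = 4),
    data.frame(id = sprintf("rs%d", 1:6), chrom = "1", pos = 1:6 * 1000,
               ref = "A", alt = c("G", "G", "T", "G", "G", "G"),
               stringsAsFactors = FALSE))
  ss <- sumstat_table(data.frame(
    snp_id = c("rs1", "badid", "rs3", "rs4", "rs4", "rs5", "rs99"),
    chrom = "1", pos = c(1:7) * 1000,
    effect_allele = c("A", "A", "A", "A", "A", "C", "A"),
    other_allele  = c("G", "G", "T", "G", "G", "G", "G"),
    beta = 0.1, se = 0.05, n = 1000,
    stringsAsFactors = FALSE), allow_duplicates = TRUE)
  out <- qc_filter(ss, pan)
  # removed: badid (no rs label), rs5 (alleles do not match the panel),
  # one duplicate rs4, rs3 (palindromic A/T), rs99 (absent from panel)
  expect_equal(sort(out$snp_id), c("rs1", "rs4"))
  qlog <- attr(out, "qc_log")
  expect_equal(unname(qlog[["rs_label"]]), 1L)
  expect_equal(unname(qlog[["allele_match"]]), 1L)
  expect_equal(unname(qlog[["duplicates"]]), 1L)
  expect_equal(unname(qlog[["palindromic"]]), 1L)
  expect_equal(unname(qlog[["panel_maf"]]), 1L)
  # MAF imputed from the panel where missing
  expect_true(all(!is.na(out$maf)))
  # idempotent (up to the log attribute)
  again <- qc_filter(out, pan)
  attr(again, "qc_log") <- attr(out, "qc_log") <- NULL
  expect_equal(as.data.frame(again), as.data.frame(out))
})

test_that("qc_filter errors when a step empties the table", {
  pan <- mk_panel(matrix(c(0, 1, 2, 1), nrow = 4, ncol = 1), ids = "rs1",
                  ref = "A", alt = "T")
  ss <- mk_ss("rs1", 0.1, 0.05, effect = "A", other = "T")  # palindromic
  expect_error(qc_filter(ss, pan), "palindromic")
})

test_that("harmonize_pair aligns alleles, flips signs, and is symmetric", {
  a <- mk_ss(c("rs1", "rs2"), c(0.2, 0.1), c(0.05, 0.05),
             effect = c("A", "A"), other = c("G", "C"))
  b <- mk_ss(c("rs1", "rs2"), c(-0.2, 0.1), c(0.05, 0.05),
             effect = c("G", "A"), other = c("A", "C"))
  hp <- harmonize_pair(a, b)
  expect_equal(hp$flipped, c(TRUE, FALSE))
  expect_equal(hp$eur$beta, c(0.2, 0.1))
  expect_equal(hp$eur$effect_allele, hp$eas$effect_allele)

  # identical tables: nothing flips, intersection equals input
  hp2 <- harmonize_pair(a, a)
  expect_false(any(hp2$flipped))
  expect_equal(as.data.frame(hp2$eur), as.data.frame(a))

  # disjoint SNP sets give an empty pair, not an error
  d <- mk_ss("rs9", 0.1, 0.05)
  hp3 <- harmonize_pair(a, d)
  expect_length(hp3$snps, 0)

  # symmetry up to roles
  hp_fwd <- harmonize_pair(a, b)
  hp_rev <- harmonize_pair(b, a)
  expect_equal(hp_rev$flipped, hp_fwd$flipped)
  expect_equal(hp_rev$eas$beta, hp_fwd$eur$beta * ifelse(hp_fwd$flipped, -1, 1))
})

test_that("irreconcilable allele pairs are dropped and counted", {
  a <- mk_ss(c("rs1", "rs2"), c(0.2, 0.1), c(0.05, 0.05),
             effect = c("A", "A"), other = c("G", "G"))
  b <- mk_ss(c("rs1", "rs2"), c(0.2, 0.1), c(0.05, 0.05),
             effect = c("A", "A"), other = c("G", "C"))
  hp <- harmonize_pair(a, b)
  expect_equal(hp$snps, "rs1")
  expect_equal(hp$n_dropped_irreconcilable, 1L)
})
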