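test_that("compute_maf counts and folds allele frequencies", {
  pan <- mk_panel(cbind(c(0, 0, 1, 1), c(2, 2, 2, 2), c(2, 2, 2, 0)))
  expect_equal(compute_maf(pan), c(0.25, 0, 0.25), ignore_attr = TRUE)
  # folding: alt frequency 0.8 -> MAF 0.2
  pan2 <- mk_panel(matrix(c(2, 2, 2, 1, 1), ncol = 1))
  expect_equal(unname(compute_maf(pan2)), 0.2)
  # all-missing SNP flagged NA
  pan3 <- mk_panel(matrix(NA_real_, 3, 1))
  expect_true(is.na(compute_maf(pan3)))
})

test_that("hwe_pass matches the chi-squared goodness of fit", {
  # 25/50/25 is perfect Hardy-Weinberg: chi2 = 0, P = 1
  d1 <- rep(c(0, 1, 2), c(25, 50, 25))
  # 50/0/50 departs maximally: chi2 equals the sample size
  d2 <- rep(c(0, 2), c(50, 50))
  pan <- mk_panel(cbind(d1, d2), ids = c("rs1", "rs2"))
  expect_equal(hwe_pass(pan, 1e-5), c(TRUE, FALSE), ignore_attr = TRUE)
  # oracle: direct chi-squared computation for the second SNP
  p_oracle <- pchisq(100, df = 1, lower.tail = FALSE)
  expect_lt(p_oracle, 1e-5)
  # monomorphic SNPs pass by convention
  pan_mono <- mk_panel(matrix(2, 10, 1))
  expect_true(hwe_pass(pan_mono))
})

test_that("ld_scores matches a brute-force windowed sum", {
  set.seed(1)
  n <- 60; m <- 30
  d <- matrix(rbinom(n * m, 2, 0.4), n, m)
  pan <- mk_panel(d, pos = seq_len(m) * 1000)
  got <- ld_scores(pan, window_bp = 5000)
  r2 <- cor(d)^2
  adj <- r2 - (1 - r2) / (n - 2)
  want <- sapply(seq_len(m), function(j) {
    k <- which(abs(seq_len(m) - j) * 1000 <= 5000)
    sum(adj[j, k])
  })
  expect_equal(got$ell, want, tolerance = 1e-12)
})

test_that("ld_scores limit cases: isolated and duplicated SNPs", {
  set.seed(2)
  x <- rbinom(50, 2, 0.5)
  pan <- mk_panel(cbind(x, x, rbinom(50, 2, 0.5)),
                  pos = c(1e3, 2e3, 5e8))  # third SNP isolated
  ell <- ld_scores(pan, window_bp = 10000)$ell
  expect_equal(ell[1], 2)      # self + perfect copy, r2 = 1 unadjusted
  expect_equal(ell[2], 2)
  expect_equal(ell[3], 1)      # self term only
  expect_error(ld_scores(pan, window_bp = 0), "positive")
})

test_that("bias adjustment subtracts (1 - r2)/(n - 2)", {
  r2 <- 0.5; n <- 502
  expect_equal(r2 - (1 - r2) / (n - 2), 0.499)
})

test_that("cross_ld_scores multiplies signed correlations across panels", {
  set.seed(3)
  n <- 80
  a <- rnorm(n)
  # panel 1: SNP2 positively correlated with SNP1; panel 2: negatively
  d1 <- cbind(rbinom(n, 2, 0.5), NA, rbinom(n, 2, 0.5))
  d1[, 2] <- d1[, 1]
  d2 <- d1
  d2[, 2] <- 2 - d2[, 1]
  pan1 <- mk_panel(d1, pos = c(1e3, 2e3, 5e8))
  pan2 <- mk_panel(d2, pos = c(1e3, 2e3, 5e8))
  lx <- cross_ld_scores(pan1, pan2, window_bp = 10000)$ell_x
  expect_equal(lx[1], 1 + 1 * (-1))   # self + (r1 = 1) * (r2 = -1)
  expect_equal(lx[3], 1)              # isolated SNP
  # identical panels: equals within-population sum of unadjusted r2
  lx_same <- cross_ld_scores(pan1, pan1, window_bp = 10000)$ell_x
  r2 <- cor(d1)^2
  expect_equal(lx_same[1], r2[1, 1] + r2[1, 2], tolerance = 1e-12)
  # mismatched SNP sets are a contract error
  expect_error(cross_ld_scores(pan1, mk_panel(d2[, 1:2, drop = FALSE])),
               "identical")
})

test_that("ld_prune keeps one of each correlated pair, preferring higher MAF", {
  set.seed(4)
  x <- rbinom(100, 2, 0.5)
  y <- rbinom(100, 2, 0.3)
  z <- rbinom(100, 2, 0.5)
  # SNP1 and SNP2 duplicated -> exactly one kept
  pan <- mk_panel(cbind(x, x, z))
  kept <- ld_prune(pan, window_snps = 10, step = 5, r2_threshold = 0.1)
  expect_length(intersect(kept, c("rs1", "rs2")), 1L)
  expect_true("rs3" %in% kept)

  # all mutually uncorrelated SNPs -> all kept
  set.seed(5)
  pan2 <- mk_panel(sapply(1:8, function(i) rbinom(200, 2, 0.5)))
  expect_length(ld_prune(pan2), 8L)

  # correlated pair: the lower-MAF member goes
  x1 <- rbinom(400, 2, 0.5)
  x2 <- x1; flip <- sample(400, 120)
  x2[flip] <- rbinom(120, 2, 0.2)   # correlated with x1, lower MAF
  pan3 <- mk_panel(cbind(x2, x1, rbinom(400, 2, 0.5)))
  maf <- compute_maf(pan3)
  r2 <- cor(pan3$dosage)^2
  if (r2[1, 2] > 0.1 && maf[1] < maf[2]) {
    kept3 <- ld_prune(pan3)
    expect_equal(sort(kept3), c("rs2", "rs3"))
  }
})

test_that("fst estimators: fixed difference, self-comparison, Hudson oracle", {
  pan_a <- mk_panel(matrix(0, 50, 1))
  pan_b <- mk_panel(matrix(2, 50, 1))
  expect_equal(unname(fst(pan_a, pan_b)), 1)
  expect_equal(unname(fst(pan_a, pan_b, "hudson")), 1)

  set.seed(6)
  pan <- mk_panel(sapply(runif(50, 0.1, 0.9), function(p) rbinom(200, 2, p)))
  self_wc <- fst(pan, pan)
  expect_lte(mean(self_wc, na.rm = TRUE), 0.005)

  # Hudson hand example with haploid-equivalent counts 100, p = 0.1 vs 0.9
  h <- transarch:::fst_hudson(0.1, 0.9, 100, 100)
  expect_equal(h, 0.77827, tolerance = 1e-5)

  # both panels monomorphic for the same allele -> undefined
  expect_true(is.na(fst(mk_panel(matrix(0, 10, 1)), mk_panel(matrix(0, 12, 1)))))
})

test_that("Weir-Cockerham Fst recovers the Balding-Nichols F", {
  cfg <- sim_config(m = 10000, fst = 0.06, seed = 2)
  fr <- simulate_frequencies(cfg)
  p1 <- simulate_genotypes(fr$p1, 504, cfg, seed = 11)
  p2 <- simulate_genotypes(fr$p2, 503, cfg, seed = 12)
  wc <- fst(p1, p2)
  expect_lt(abs(mean(wc, na.rm = TRUE) - 0.06), 0.01)
})

test_that("mhc_mask excludes exactly chr6:28.5-33.5 Mb", {
  meta <- data.frame(chrom = c("6", "6", "6", "7", "chr6"),
                     pos = c(30e6, 28499999, 33500001, 30e6, 28500000))
  expect_equal(mhc_mask(meta), c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("panels round-trip through VCF", {
  set.seed(7)
  d <- matrix(rbinom(60, 2, 0.4), 10, 6)
  d[1, 2] <- NA
  pan <- mk_panel(d)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(pan, f)
  back <- read_panel_vcf(f)
  expect_equal(back$dosage, pan$dosage, ignore_attr = TRUE)
  expect_equal(back$snp_meta$id, pan$snp_meta$id)
  expect_equal(back$sample_ids, pan$sample_ids)
})

test_that("independent simulated SNPs give mean LD score about 1", {
  cfg <- sim_config(m = 1000, ld_rho = 0, seed = 4)
  pan <- simulate_genotypes(simulate_frequencies(cfg)$p1, 500, cfg, seed = 9)
  ell <- ld_scores(pan)$ell
  expect_lt(abs(mean(ell) - 1), 0.05)
  # with few neighbours per window the score stays near its floor of 1
  ell_narrow <- ld_scores(pan, window_bp = 25000)$ell
  expect_true(all(ell_narrow >= 0.8))
})
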