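test_that("frequencies follow the Balding-Nichols construction", {
  cfg0 <- sim_config(m = 2000, fst = 0, seed = 2)
  fr0 <- simulate_frequencies(cfg0)
  expect_equal(fr0$p1, fr0$p_anc)
  expect_equal(fr0$p2, fr0$p_anc)

  cfg <- sim_config(m = 5000, fst = 0.06, seed = 2)
  fr <- simulate_frequencies(cfg)
  expect_true(all(fr$p1 > 0.01 & fr$p1 < 0.99))
  expect_true(all(fr$p2 > 0.01 & fr$p2 < 0.99))
  expect_true(all(fr$p_anc >= 0.05 & fr$p_anc <= 0.95))
  # differentiation grows with F
  cfg_hi <- sim_config(m = 5000, fst = 0.2, seed = 2)
  fr_hi <- simulate_frequencies(cfg_hi)
  expect_gt(mean((fr_hi$p1 - fr_hi$p2)^2), mean((fr$p1 - fr$p2)^2))
})

test_that("group labels hit their proportions and effects respect them", {
  cfg <- sim_config(m = 20000, seed = 3)
  truth <- assign_effects(cfg)
  tab <- table(truth$group) / nrow(truth)
  for (i in seq_along(cfg$pi)) {
    lab <- c("null", "eas_specific", "eur_specific", "common")[i]
    got <- if (lab %in% names(tab)) tab[[lab]] else 0
    sd3 <- 3 * sqrt(cfg$pi[i] * (1 - cfg$pi[i]) / cfg$m)
    expect_lt(abs(got - cfg$pi[i]), sd3 + 1e-9)
  }
  # zero effects exactly where the label implies none
  expect_true(all(truth$beta1_std[truth$group %in% c("null", "eur_specific")] == 0))
  expect_true(all(truth$beta2_std[truth$group %in% c("null", "eas_specific")] == 0))
  # per-population genetic variance equals the configured heritability
  expect_equal(sum(truth$beta1_std^2), cfg$h2_1, tolerance = 1e-12)
  expect_equal(sum(truth$beta2_std^2), cfg$h2_2, tolerance = 1e-12)
})

test_that("all-null and perfectly shared architectures behave", {
  cfg0 <- sim_config(m = 1000, pi = c(1, 0, 0, 0), h2_1 = 0, h2_2 = 0, seed = 4)
  truth0 <- assign_effects(cfg0)
  expect_true(all(truth0$beta1_std == 0))
  expect_true(is.na(attr(truth0, "rho_g_true")))

  cfg1 <- sim_config(m = 20000, pi = c(0.5, 0, 0, 0.5), rho_shared = 1, seed = 4)
  truth1 <- assign_effects(cfg1)
  shared <- truth1$group == "common"
  b1 <- truth1$beta1_std[shared] / sqrt(cfg1$h2_1)
  b2 <- truth1$beta2_std[shared] / sqrt(cfg1$h2_2)
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("shared-causal effect correlation matches rho_shared", {
  cfg <- sim_config(m = 30000, pi = c(0.8, 0.05, 0.05, 0.10),
                    rho_shared = 0.8, seed = 5)
  truth <- assign_effects(cfg)
  shared <- truth$group == "common"
  expect_gt(sum(shared), 1000)
  expect_lt(abs(cor(truth$beta1_std[shared], truth$beta2_std[shared]) - 0.8),
            0.05)
})

test_that("blockwise copula produces LD inside blocks, none between", {
  cfg <- sim_config(m = 200, ld_rho = 0.8, block_size = 10, seed = 6)
  fr <- simulate_frequencies(cfg)
  pan <- simulate_genotypes(fr$p1, 500, cfg, seed = 21)
  r <- cor(pan$dosage)
  within <- abs(r[cbind(1:199, 2:200)])[(1:199) %% 10 != 0]
  between <- abs(r[cbind(seq(10, 190, 10), seq(11, 191, 10))])
  expect_gt(mean(within), mean(between) + 0.2)
  # no-LD limit: adjacent correlations are just noise
  cfg0 <- sim_config(m = 200, ld_rho = 0, seed = 6)
  pan0 <- simulate_genotypes(fr$p1, 500, cfg0, seed = 21)
  r0 <- cor(pan0$dosage)
  expect_lt(mean(abs(r0[cbind(1:199, 2:200)])), 0.05)
  # empirical frequencies track their targets
  expect_lt(max(abs(colMeans(pan0$dosage) / 2 - fr$p1)), 4 * sqrt(0.25 / 1000))
})

test_that("null summary statistics are calibrated", {
  cfg <- sim_config(m = 10000, pi = c(1, 0, 0, 0), h2_1 = 0, h2_2 = 0, seed = 7)
  st <- simulate_study(cfg, panels = FALSE)
  expect_lt(abs(mean(st$ss_eas$z^2) - 1), 0.05)
  expect_equal(st$ss_eas$z, st$ss_eas$beta / st$ss_eas$se, tolerance = 1e-9)
})

test_that("analytic and explicit phenotype routes agree", {
  cfg <- sim_config(m = 2000, n1 = 2000, n2 = 2000, ld_rho = 0,
                    h2_1 = 0.3, h2_2 = 0.3, seed = 8)
  fr <- simulate_frequencies(cfg)
  truth <- assign_effects(cfg, fr)
  a <- simulate_sumstats(truth, fr, 2000, 1L)
  b <- simulate_sumstats_explicit(truth, fr, 2000, 1L)
  expect_lt(abs(mean(a$z) - mean(b$z)), 0.05)
  expect_lt(abs(mean(a$z^2) - mean(b$z^2)), 0.2)
  # both recover the expected noncentrality at causal SNPs
  causal <- truth$beta1_std != 0
  expect_gt(cor(a$z[causal], sqrt(2000) * truth$beta1_std[causal]), 0.5)
  expect_gt(cor(b$z[causal], sqrt(2000) * truth$beta1_std[causal]), 0.5)
})

test_that("fixtures are deterministic and self-contained", {
  cfg <- sim_config(m = 300, n_ref = c(60, 60), ld_rho = 0.5, block_size = 5,
                    seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture(cfg, d1)
  p2 <- make_fixture(cfg, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  ss <- read_sumstats(p1[["sumstats_eas"]], std_dialect, sep = "\t")
  pan <- read_panel_vcf(p1[["panel_eas"]])
  expect_equal(nrow(ss), 300)
  expect_equal(nrow(pan$snp_meta), 300)
  cfg_back <- yaml::read_yaml(p1[["config"]])
  expect_equal(cfg_back$seed, 9)
  truth <- read.delim(p1[["truth"]])
  expect_equal(sort(unique(truth$group)),
               sort(unique(c("null", "eas_specific", "eur_specific", "common"))))
})

test_that("seed streams are independent and reproducible", {
  cfg <- sim_config(m = 500, seed = 10)
  f1 <- simulate_frequencies(cfg)
  f2 <- simulate_frequencies(cfg)
  expect_identical(f1, f2)
  # a different stage does not disturb the frequency stream
  invisible(assign_effects(cfg))
  expect_identical(simulate_frequencies(cfg), f1)
  # different master seeds decouple
  expect_false(identical(simulate_frequencies(sim_config(m = 500, seed = 11)),
                         f1))
})
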