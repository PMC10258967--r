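test_that("whitening matrix is the symmetric inverse square root", {
  w <- whitening_matrix(0.6)
  expect_equal(w, matrix(c(1.18585, -0.39528, -0.39528, 1.18585), 2),
               tolerance = 1e-5)
  for (r in c(-0.8, -0.3, 0, 0.3, 0.6, 0.95)) {
    w <- whitening_matrix(r)
    c2 <- matrix(c(1, r, r, 1), 2)
    expect_equal(w %*% c2 %*% t(w), diag(2), tolerance = 1e-8)
    expect_equal(w, t(w))
  }
  expect_equal(whitening_matrix(0), diag(2))
  expect_error(whitening_matrix(1), "< 1")
})

test_that("decorrelate transforms Z and recomputes two-sided P", {
  ss <- mk_ss(c("rs1", "rs2"), c(0.1, 0.1), c(0.05, 0.05))
  ss$z <- c(2, -1); ss$p <- two_sided_p(ss$z)
  pair <- mk_pair(ss, ss)
  # identity model leaves everything unchanged
  ident <- structure(list(r_null = 0, transform = diag(2)),
                     class = "decorrelation_model")
  dz <- decorrelate(pair, ident)
  expect_equal(dz$z1, pair$eas$z)
  expect_equal(dz$p1, pair$eas$p)
  # hand example: z = (2, 2) with r = 0.6 maps to (1.58114, 1.58114)
  m6 <- structure(list(r_null = 0.6, transform = whitening_matrix(0.6)),
                  class = "decorrelation_model")
  ssb <- ss; ssb$z <- c(2, 2); ssb$p <- two_sided_p(ssb$z)
  dz6 <- decorrelate(mk_pair(ssb, ssb), m6)
  expect_equal(dz6$z1[1], 1.58114, tolerance = 1e-5)
  expect_equal(dz6$p1, two_sided_p(dz6$z1))
})

test_that("null correlation is estimated from jointly null SNPs and removed", {
  n <- 100000
  set.seed(31)
  r <- 0.3
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  ss1 <- mk_ss(sprintf("rs%d", 1:n), 0.1, 0.05)
  ss1$z <- z1; ss1$p <- two_sided_p(z1)
  ss2 <- ss1; ss2$z <- z2; ss2$p <- two_sided_p(z2)
  pair <- mk_pair(ss1, ss2)
  model <- estimate_null_correlation(pair)
  expect_equal(model$r_null, r, tolerance = 0.02)
  dz <- decorrelate(pair, model)
  nullset <- dz$p1 > 1e-4 & dz$p2 > 1e-4
  expect_lt(abs(cor(dz$z1[nullset], dz$z2[nullset])), 0.02)
  # too few null SNPs is an explicit error
  tiny <- mk_pair(ss1[1:50, ], ss2[1:50, ])
  expect_error(estimate_null_correlation(tiny), "loosen")
})

test_that("empirical cFDR matches brute-force counting", {
  p1 <- c(0.001, 0.2, 0.5, 0.8, 0.9)
  p2 <- c(0.002, 0.3, 0.4, 0.7, 0.95)
  tab <- empirical_cfdr(p1, p2)
  expect_equal(tab$cfdr_1g2[1], 0.001)  # 0.001 * 1 / 1
  brute <- sapply(1:5, function(i)
    min(1, p1[i] * sum(p2 <= p2[i]) / sum(p1 <= p1[i] & p2 <= p2[i])))
  expect_equal(tab$cfdr_1g2, brute)

  set.seed(32)
  n <- 400
  q1 <- runif(n)^2
  q2 <- pmin(1, round(runif(n), 2) + 0.005)  # heavy ties
  tab2 <- empirical_cfdr(q1, q2)
  b1 <- sapply(seq_len(n), function(i)
    min(1, q1[i] * sum(q2 <= q2[i]) / sum(q1 <= q1[i] & q2 <= q2[i])))
  b2 <- sapply(seq_len(n), function(i)
    min(1, q2[i] * sum(q1 <= q1[i]) / sum(q1 <= q1[i] & q2 <= q2[i])))
  expect_equal(tab2$cfdr_1g2, b1)
  expect_equal(tab2$cfdr_2g1, b2)
  expect_equal(tab2$ccfdr, pmax(tab2$cfdr_1g2, tab2$cfdr_2g1))
})

test_that("cFDR invariants: bounds, p = 1 limit, swap symmetry", {
  set.seed(33)
  n <- 2000
  p1 <- runif(n)^3; p2 <- runif(n)
  p1[1] <- 1
  tab <- empirical_cfdr(p1, p2)
  expect_true(all(tab$ccfdr >= pmax(tab$cfdr_1g2, tab$cfdr_2g1) - 1e-15))
  expect_true(all(tab$cfdr_1g2 >= tab$p1 - 1e-15))  # conservative pi0 = 1
  expect_true(all(tab$cfdr_1g2 >= 0 & tab$cfdr_1g2 <= 1))
  expect_equal(tab$cfdr_1g2[1], 1)
  swapped <- empirical_cfdr(p2, p1)
  expect_equal(swapped$cfdr_1g2, tab$cfdr_2g1)
  expect_equal(swapped$cfdr_2g1, tab$cfdr_1g2)
  expect_equal(swapped$ccfdr, tab$ccfdr)
  expect_error(empirical_cfdr(numeric(0), numeric(0)), "non-empty")
  expect_error(empirical_cfdr(c(0, 0.5), c(0.5, 0.5)), "\\(0, 1\\]")
})

test_that("classification follows the max rule and partitions SNPs", {
  tab <- data.frame(snp_id = c("a", "b", "c", "d"),
                    cfdr_1g2 = c(0.01, 0.01, 0.20, 0.04),
                    cfdr_2g1 = c(0.04, 0.20, 0.30, 0.01))
  tab$ccfdr <- pmax(tab$cfdr_1g2, tab$cfdr_2g1)
  cls <- classify_snps(tab, alpha = 0.05)
  expect_equal(cls$label, c("common", "eas_specific", "null", "common"))
  expect_equal(cls$k, 4L)
  expect_equal(cls$f11, 2L); expect_equal(cls$f10, 1L); expect_equal(cls$f01, 0L)
  expect_error(classify_snps(tab, alpha = 1.2), "alpha")
})

test_that("classification count identities hold on random tables", {
  set.seed(34)
  for (rep in 1:5) {
    n <- 500
    tab <- data.frame(snp_id = paste0("s", 1:n),
                      cfdr_1g2 = runif(n)^2, cfdr_2g1 = runif(n)^2)
    tab$ccfdr <- pmax(tab$cfdr_1g2, tab$cfdr_2g1)
    a <- 0.05
    cls <- classify_snps(tab, a)
    expect_equal(cls$f10 + cls$f01 + cls$f11 + sum(cls$label == "null"), cls$k)
    expect_equal(cls$f10 + cls$f11, sum(tab$cfdr_1g2 < a))
    expect_equal(cls$f01 + cls$f11, sum(tab$cfdr_2g1 < a))
    expect_equal(cls$f11, sum(tab$ccfdr < a))
    # monotone thresholding: the common set shrinks with alpha
    strict <- classify_snps(tab, 0.01)
    common_strict <- strict$snp_id[strict$label == "common"]
    common_loose <- cls$snp_id[cls$label == "common"]
    expect_true(all(common_strict %in% common_loose))
  }
})

test_that("min-P baseline calls obvious cases and respects BH", {
  p1 <- c(1e-9, 1e-9, 0.5)
  p2 <- c(1e-9, 0.9, 0.6)
  called <- minp_baseline(p1, p2, alpha = 0.05)
  expect_equal(called, c(TRUE, FALSE, FALSE))
})
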