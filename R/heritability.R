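## LD-score regression machinery shared by the heritability and genetic
## correlation estimators. The same two-step weighted regression engine is
## used throughout so that the self-correlation of a trait with itself is
## exactly 1.

wls_fit <- function(y, x, w, intercept = TRUE, null_value = 0) {
  if (intercept) {
    sx <- sum(w * x); sy <- sum(w * y); sw <- sum(w)
    sxx <- sum(w * x^2); sxy <- sum(w * x * y)
    det <- sw * sxx - sx^2
    if (det <= .Machine$double.eps * sw * sxx || stats::var(x) < 1e-12 * mean(x)^2) {
      # constant regressor: pin the intercept at its null expectation and
      # read the slope off the mean excess
      if (sxx == 0) stop("wls_fit: regressor is identically zero")
      b <- sum(w * (y - null_value) * x) / sxx
      return(c(intercept = null_value, slope = b))
    }
    b <- (sw * sxy - sx * sy) / det
    a <- (sy - b * sx) / sw
    c(intercept = a, slope = b)
  } else {
    sxx <- sum(w * x^2)
    if (sxx == 0) stop("wls_fit: regressor is identically zero")
    c(intercept = 0, slope = sum(w * x * y) / sxx)
  }
}

block_assign <- function(n, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, n))
  sort(rep_len(seq_len(n_blocks), n))
}

# Delete-a-block jackknife of an arbitrary statistic fun(keep_index).
jackknife_blocks <- function(n, n_blocks, fun) {
  blk <- block_assign(n, n_blocks)
  b <- max(blk)
  est <- vapply(seq_len(b), function(k) fun(which(blk != k)), numeric(1L))
  se <- sqrt((b - 1) / b * sum((est - mean(est))^2))
  list(se = se, n_blocks = b, leave_one_out = est)
}

# Core cross-score regression: regress z1*z2 on sqrt(n1*n2)*ell_reg/m with
# LDSC-style weights. For z1 == z2 this is the chi-square heritability
# regression. ell_w carries the within-population LD scores used for the
# heteroskedasticity weights (a two-column matrix or a vector).
ldsc_pair_regression <- function(z1, z2, n1, n2, ell_reg, ell_w1, ell_w2,
                                 m, intercept = TRUE, n_blocks = 200L) {
  nsnp <- length(z1)
  stopifnot(length(z2) == nsnp, length(ell_reg) == nsnp)
  same <- identical(z1, z2) && identical(n1, n2)
  null_value <- if (same) 1 else 0
  n1 <- as.numeric(n1); n2 <- as.numeric(n2)  # guard integer overflow in n1*n2
  x <- sqrt(n1) * sqrt(n2) * ell_reg / m
  base_w <- 1 / pmax((ell_w1 + ell_w2) / 2, 1)
  # first pass: crude per-trait heritabilities for the variance weights
  w0 <- base_w
  h1_0 <- max(0, wls_fit(z1^2, n1 * ell_w1 / m, 1 / pmax(ell_w1, 1),
                         intercept = TRUE, null_value = 1)[["slope"]])
  h2_0 <- if (same) h1_0 else {
    max(0, wls_fit(z2^2, n2 * ell_w2 / m, 1 / pmax(ell_w2, 1),
                   intercept = TRUE, null_value = 1)[["slope"]])
  }
  w <- base_w / ((1 + h1_0 * n1 * ell_w1 / m) * (1 + h2_0 * n2 * ell_w2 / m))
  y <- z1 * z2
  full <- wls_fit(y, x, w, intercept = intercept, null_value = null_value)
  if (nsnp < 10L * n_blocks) {
    n_blocks <- max(2L, nsnp %/% 10L)
    warning("ldsc regression: fewer SNPs than 10 x blocks; using ",
            n_blocks, " jackknife blocks")
  }
  jk_slope <- jackknife_blocks(nsnp, n_blocks, function(idx) {
    wls_fit(y[idx], x[idx], w[idx], intercept = intercept,
            null_value = null_value)[["slope"]]
  })
  jk_int <- if (intercept) {
    jackknife_blocks(nsnp, n_blocks, function(idx) {
      wls_fit(y[idx], x[idx], w[idx], intercept = intercept,
              null_value = null_value)[["intercept"]]
    })
  } else list(se = NA_real_, n_blocks = jk_slope$n_blocks)
  list(slope = full[["slope"]], intercept = full[["intercept"]],
       slope_se = jk_slope$se, intercept_se = jk_int$se,
       n_blocks = jk_slope$n_blocks, m = m, weights = w,
       slope_loo = jk_slope$leave_one_out)
}

#' LD-score-regression heritability
#'
#' Regresses the per-SNP chi-squared statistic on `N * ell / m` with a free
#' intercept; the slope estimates the SNP heritability on the observed
#' scale and the intercept captures confounding (1 in its absence).
#' Weights are `1 / max(ell, 1)` iterated once with the standard
#' heteroskedasticity weight; the standard error comes from a
#' delete-a-block jackknife over contiguous SNP blocks. Input SNPs should
#' be QC'd and MHC-masked. If the regressor is constant (no LD variation
#' and constant N) the intercept is pinned at 1 and the slope is the mean
#' excess chi-square, with a warning.
#'
#' @param ss a [sumstat_table] with `z` and `n` filled.
#' @param ld data.frame with `snp_id` and `ell` (see [ld_scores()]).
#' @param m number of SNPs the heritability is spread over (defaults to
#'   the number of regression SNPs).
#' @param n_blocks jackknife block count (default 200).
#' @return list of class `h2_estimate`: `h2`, `se`, `intercept`,
#'   `intercept_se`, `m`, `n_blocks`.
#' @export
estimate_h2 <- function(ss, ld, m = NULL, n_blocks = 200L) {
  idx <- match(ss$snp_id, ld$snp_id)
  if (anyNA(idx)) stop("estimate_h2: ", sum(is.na(idx)), " SNP(s) lack LD scores")
  ell <- ld$ell[idx]
  if (is.null(m)) m <- length(ell)
  if (stats::var(ell) < 1e-12 && stats::var(ss$n) > 0) {
    # fine: regressor still varies through N
  } else if (stats::var(ss$n * ell) < 1e-12 * mean(ss$n * ell)^2) {
    warning("estimate_h2: constant regressor; intercept pinned at 1 and ",
            "slope read from the mean excess chi-square")
  }
  fit <- ldsc_pair_regression(ss$z, ss$z, ss$n, ss$n, ell, ell, ell,
                              m = m, intercept = TRUE, n_blocks = n_blocks)
  structure(list(h2 = fit$slope, se = fit$slope_se,
                 intercept = fit$intercept, intercept_se = fit$intercept_se,
                 m = m, n_blocks = fit$n_blocks),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.4f (se %.4f), intercept = %.3f (se %.3f), m = %d, blocks = %d\n",
              x$h2, x$se, x$intercept, x$intercept_se, x$m, x$n_blocks))
  invisible(x)
}

#' Cross-trait genetic correlation within one population
#'
#' Regresses the product `z1 * z2` of two traits' statistics on
#' `sqrt(N1 N2) * ell / m` with a free intercept (which absorbs sample
#' overlap); the slope estimates the genetic covariance, divided by the
#' geometric mean of the two heritabilities to give the correlation.
#'
#' @param ss1,ss2 [sumstat_table]s on identical SNPs in identical order.
#' @param ld data.frame with `snp_id` and `ell`.
#' @param h2_1,h2_2 `h2_estimate`s for the two traits (both must be > 0).
#' @param m,n_blocks as in [estimate_h2()].
#' @return list of class `rg_estimate`: `rg`, `se`, `gencov`,
#'   `gencov_se`, `intercept`.
#' @export
cross_trait_rg_within_pop <- function(ss1, ss2, ld, h2_1, h2_2,
                                      m = NULL, n_blocks = 200L) {
  if (!identical(ss1$snp_id, ss2$snp_id)) {
    stop("cross_trait_rg_within_pop: SNP sets must be identical and aligned")
  }
  if (h2_1$h2 <= 0 || h2_2$h2 <= 0) {
    stop("cross_trait_rg_within_pop: correlation undefined for non-positive h2")
  }
  idx <- match(ss1$snp_id, ld$snp_id)
  if (anyNA(idx)) stop("cross_trait_rg_within_pop: missing LD scores")
  ell <- ld$ell[idx]
  if (is.null(m)) m <- length(ell)
  fit <- ldsc_pair_regression(ss1$z, ss2$z, ss1$n, ss2$n, ell, ell, ell,
                              m = m, intercept = TRUE, n_blocks = n_blocks)
  denom <- sqrt(h2_1$h2 * h2_2$h2)
  structure(list(rg = fit$slope / denom, se = fit$slope_se / denom,
                 gencov = fit$slope, gencov_se = fit$slope_se,
                 intercept = fit$intercept, n_blocks = fit$n_blocks),
            class = "rg_estimate")
}

#' Approximate normal test for a heritability difference
#'
#' `u = (h2_1 - h2_2) / sqrt(se_1^2 + se_2^2)`, with a two-sided standard
#' normal P value and optional Benjamini-Hochberg adjustment across the
#' supplied family of tests. All arguments are vectorized across traits.
#'
#' @param h2_1,se_1,h2_2,se_2 estimates and standard errors (se > 0).
#' @param adjust apply BH across the supplied vector (default `TRUE`).
#' @return data.frame with `u`, `p` and (if `adjust`) `p_adjusted`.
#' @export
h2_diff_test <- function(h2_1, se_1, h2_2, se_2, adjust = TRUE) {
  if (any(se_1 <= 0 | se_2 <= 0)) {
    stop("h2_diff_test: standard errors must be positive")
  }
  u <- (h2_1 - h2_2) / sqrt(se_1^2 + se_2^2)
  p <- two_sided_p(u)
  out <- data.frame(u = u, p = p)
  if (adjust) out$p_adjusted <- stats::p.adjust(p, method = "BH")
  out
}

#' Two-value coefficient of variation
#'
#' Sample (n-1) standard deviation of the two values divided by their
#' mean: `(|a - b| / sqrt(2)) / ((a + b) / 2)`. Used for LDCV, MAFCV and
#' NCV alike; scale-free. Both-zero pairs are returned as `NA`.
#'
#' @param a,b non-negative values (vectorized).
#' @return coefficient(s) of variation.
#' @export
two_value_cv <- function(a, b) {
  if (any(a < 0 | b < 0, na.rm = TRUE)) {
    stop("two_value_cv: values must be non-negative")
  }
  mu <- (a + b) / 2
  out <- (abs(a - b) / sqrt(2)) / mu
  out[!is.na(mu) & mu == 0] <- NA_real_
  out
}

#' Sample-size coefficient of variation (NCV)
#'
#' The two-value CV of a trait's sample sizes in the two populations.
#'
#' @param n1,n2 positive sample sizes (vectorized).
#' @return coefficient(s) of variation.
#' @export
ncv <- function(n1, n2) {
  if (any(n1 <= 0 | n2 <= 0)) stop("ncv: sample sizes must be positive")
  two_value_cv(n1, n2)
}

#' Effective sample size for a binary trait
#'
#' `4 / (1 / n_cases + 1 / n_controls)`, the equivalent balanced-design
#' sample size used wherever N enters the score regressions.
#'
#' @param n_cases,n_controls case and control counts.
#' @return effective sample size.
#' @export
effective_n <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}
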