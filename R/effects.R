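#' Measurement-error-corrected correlation of marginal effect sizes
#'
#' The naive Pearson correlation of estimated effect sizes is attenuated
#' toward zero because both coordinates carry estimation noise. Under a
#' measurement-error model the correction divides the covariance by the
#' geometric mean of the error-free variances,
#' `r_m = cov(b1, b2) / sqrt((var(b1) - mean(se1^2)) * (var(b2) -
#' mean(se2^2)))`, which is unbiased when the errors are independent
#' across populations (no shared samples). The standard error comes from
#' a delete-one jackknife over SNPs.
#'
#' @param beta1,se1,beta2,se2 aligned per-SNP effect estimates and
#'   standard errors (>= 10 SNPs).
#' @return list of class `marginal_correlation`: `r_m`, `se`, `n_snps`,
#'   `naive_r`, `undefined` (TRUE when a corrected variance is
#'   non-positive, with diagnostics).
#' @export
magic_corr <- function(beta1, se1, beta2, se2) {
  n <- length(beta1)
  if (n < 10L) stop("magic_corr: need at least 10 SNPs")
  stopifnot(length(se1) == n, length(beta2) == n, length(se2) == n)
  point <- magic_point(beta1, se1, beta2, se2)
  if (is.na(point$r_m)) {
    return(structure(list(r_m = NA_real_, se = NA_real_, n_snps = n,
                          naive_r = point$naive, undefined = TRUE,
                          corrected_var1 = point$v1, corrected_var2 = point$v2),
                     class = "marginal_correlation"))
  }
  # delete-one jackknife via streaming sums
  s1 <- sum(beta1); s2 <- sum(beta2)
  s11 <- sum(beta1^2); s22 <- sum(beta2^2); s12 <- sum(beta1 * beta2)
  e1 <- sum(se1^2); e2 <- sum(se2^2)
  k <- n - 1L
  cov_i <- (s12 - beta1 * beta2 - (s1 - beta1) * (s2 - beta2) / k) / (k - 1L)
  v1_i <- (s11 - beta1^2 - (s1 - beta1)^2 / k) / (k - 1L) - (e1 - se1^2) / k
  v2_i <- (s22 - beta2^2 - (s2 - beta2)^2 / k) / (k - 1L) - (e2 - se2^2) / k
  ok <- v1_i > 0 & v2_i > 0
  r_i <- rep(point$r_m, n)
  r_i[ok] <- cov_i[ok] / sqrt(v1_i[ok] * v2_i[ok])
  se <- sqrt((n - 1L) / n * sum((r_i - mean(r_i))^2))
  structure(list(r_m = point$r_m, se = se, n_snps = n,
                 naive_r = point$naive, undefined = FALSE),
            class = "marginal_correlation")
}

magic_point <- function(beta1, se1, beta2, se2) {
  v1 <- stats::var(beta1) - mean(se1^2)
  v2 <- stats::var(beta2) - mean(se2^2)
  naive <- stats::cor(beta1, beta2)
  if (v1 <= 0 || v2 <= 0) {
    return(list(r_m = NA_real_, naive = naive, v1 = v1, v2 = v2))
  }
  list(r_m = stats::cov(beta1, beta2) / sqrt(v1 * v2),
       naive = naive, v1 = v1, v2 = v2)
}

#' @export
print.marginal_correlation <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("marginal correlation undefined: corrected variances %.3g, %.3g (naive r = %.3f, n = %d)\n",
                x$corrected_var1, x$corrected_var2, x$naive_r, x$n_snps))
  } else {
    cat(sprintf("r_m = %.3f (se %.3f), naive Pearson = %.3f, n = %d SNPs\n",
                x$r_m, x$se, x$naive_r, x$n_snps))
  }
  invisible(x)
}

#' No-intercept regression of effect sizes between populations
#'
#' Regresses the effect sizes of population-common SNPs in one population
#' on those in the other without an intercept:
#' `slope = sum(b1 * b2) / sum(b2^2)` with `b1` the response. A Wald
#' two-sided test of slope = 1 indicates whether shared associations have
#' the same magnitude in both populations.
#'
#' @param beta1 response effect sizes (>= 3 SNPs).
#' @param beta2 predictor effect sizes.
#' @return list with `slope`, `se`, `t`, `p_vs1`, `n_snps`.
#' @export
slope_no_intercept <- function(beta1, beta2) {
  n <- length(beta1)
  if (n < 3L) stop("slope_no_intercept: need at least 3 SNPs")
  sxx <- sum(beta2^2)
  if (sxx == 0) stop("slope_no_intercept: predictor effects are all zero")
  slope <- sum(beta1 * beta2) / sxx
  resid <- beta1 - slope * beta2
  se <- sqrt(sum(resid^2) / (n - 1L) / sxx)
  if (se == 0) {  # exact fit: the test degenerates to an equality check
    return(list(slope = slope, se = 0, t = if (slope == 1) 0 else Inf,
                p_vs1 = if (slope == 1) 1 else 0, n_snps = n))
  }
  tstat <- (slope - 1) / se
  list(slope = slope, se = se, t = tstat,
       p_vs1 = 2 * stats::pt(-abs(tstat), df = n - 1L), n_snps = n)
}

#' Per-SNP Cochran's Q heterogeneity test across two populations
#'
#' For two studies the inverse-variance-weighted Q statistic reduces to
#' `(b1 - b2)^2 / (se1^2 + se2^2)`, referred to chi-squared with 1 degree
#' of freedom. Significance is declared after Bonferroni correction over
#' the SNPs tested. Intended for population-common associated SNPs;
#' population-specific SNPs are heterogeneous by definition and should
#' not be tested.
#'
#' @param beta1,se1,beta2,se2 aligned per-SNP estimates (se > 0).
#' @param alpha family-wise level for the Bonferroni flag (default 0.05).
#' @return list of class `heterogeneity_result` with per-SNP `q`, `p`,
#'   `significant`, and `prop_het`.
#' @export
cochran_q <- function(beta1, se1, beta2, se2, alpha = 0.05) {
  if (any(se1 <= 0 | se2 <= 0)) stop("cochran_q: standard errors must be positive")
  q <- (beta1 - beta2)^2 / (se1^2 + se2^2)
  p <- stats::pchisq(q, df = 1L, lower.tail = FALSE)
  sig <- p < alpha / length(q)
  structure(list(q = q, p = p, significant = sig,
                 prop_het = mean(sig), n_tested = length(q)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q on %d SNPs: %.1f%% heterogeneous after Bonferroni\n",
              x$n_tested, 100 * x$prop_het))
  invisible(x)
}
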