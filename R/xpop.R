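#' Trans-ethnic genetic-effect correlation from paired summary statistics
#'
#' Estimates the correlation of per-SNP (standardized) genetic effects of
#' one trait between two ancestral populations by regressing the product
#' `z1 * z2` on `sqrt(N1 N2) * ell_x / m` without an intercept, where
#' `ell_x` is the cross-population LD score. The two GWAS share no
#' samples, so the cross products have zero expectation under the null
#' and no intercept is fitted. The slope estimates the genetic-effect
#' covariance; dividing by the geometric mean heritability gives the
#' correlation. The estimate is deliberately unbounded: values outside
#' `[-1, 1]` are flagged (`out_of_range`), never clipped.
#'
#' This is a method-of-moments estimator of the genetic-effect
#' correlation estimand; it shares the estimand, not the fitting, with
#' Bayesian trans-ethnic correlation software.
#'
#' @param pair a [harmonize_pair()] result (both populations aligned).
#' @param ld1,ld2 within-population LD score tables (`snp_id`, `ell`)
#'   used for the regression weights.
#' @param ldx cross-population LD score table (`snp_id`, `ell_x`).
#' @param h2_1,h2_2 `h2_estimate`s for the trait in each population;
#'   both must be positive.
#' @param m,n_blocks as in [estimate_h2()].
#' @return list of class `xpop_estimate`: `rho_g`, `se`, `p_vs0`,
#'   `p_vs1`, `gencov`, `out_of_range`.
#' @export
trans_ethnic_rg <- function(pair, ld1, ld2, ldx, h2_1, h2_2,
                            m = NULL, n_blocks = 200L) {
  if (h2_1$h2 <= 0) stop("trans_ethnic_rg: non-positive h2 in population 1")
  if (h2_2$h2 <= 0) stop("trans_ethnic_rg: non-positive h2 in population 2")
  snps <- pair$snps
  i1 <- match(snps, ld1$snp_id)
  i2 <- match(snps, ld2$snp_id)
  ix <- match(snps, ldx$snp_id)
  if (anyNA(i1) || anyNA(i2) || anyNA(ix)) {
    stop("trans_ethnic_rg: SNP sets of LD score tables must cover the pair")
  }
  ell1 <- ld1$ell[i1]; ell2 <- ld2$ell[i2]; ellx <- ldx$ell_x[ix]
  if (is.null(m)) m <- length(snps)
  fit <- ldsc_pair_regression(pair$eas$z, pair$eur$z,
                              pair$eas$n, pair$eur$n,
                              ellx, ell1, ell2,
                              m = m, intercept = FALSE, n_blocks = n_blocks)
  denom <- sqrt(h2_1$h2 * h2_2$h2)
  rho <- fit$slope / denom
  se <- fit$slope_se / denom
  structure(list(rho_g = rho, se = se,
                 p_vs0 = two_sided_p(rho / se),
                 p_vs1 = two_sided_p((rho - 1) / se),
                 gencov = fit$slope, gencov_se = fit$slope_se,
                 out_of_range = abs(rho) > 1,
                 n_blocks = fit$n_blocks),
            class = "xpop_estimate")
}

#' @export
print.xpop_estimate <- function(x, ...) {
  if (!is.null(x$error)) {
    cat("rho_g unavailable:", x$error, "\n")
    return(invisible(x))
  }
  cat(sprintf("rho_g = %.3f (se %.3f), P(vs 0) = %.3g, P(vs 1) = %.3g%s\n",
              x$rho_g, x$se, x$p_vs0, x$p_vs1,
              if (x$out_of_range) " [outside [-1,1]]" else ""))
  invisible(x)
}
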