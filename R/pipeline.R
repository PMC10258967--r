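#' Run the full trans-ethnic comparison for one trait
#'
#' Sequences the whole analysis for one trait from paired summary
#' statistics and two reference panels: QC and harmonization, LD scores
#' (MHC-masked, MAF/HWE-filtered contributing set), heritability in each
#' population, trans-ethnic genetic-effect correlation, LD pruning and
#' Z decorrelation, cFDR/ccFDR and four-way classification, the
#' four-group mixture fit, effect-size concordance and heterogeneity,
#' divergence statistics (LDCV, MAFCV, Fst with Kruskal-Wallis group
#' comparisons) and the three genetic risk scores.
#'
#' @param ss_eas,ss_eur [sumstat_table]s for the two populations.
#' @param panel_eas,panel_eur reference [genotype_panel]s.
#' @param trait_type `"continuous"` or `"binary"` (drives GRS rescaling).
#' @param alpha cFDR/ccFDR significance level (default 0.05).
#' @param null_p_threshold P threshold defining null SNPs for the Z
#'   decorrelation (default `1e-4`).
#' @param maf_min,hwe_p QC thresholds (defaults 0.01 and `1e-5`).
#' @param prune_window,prune_step,prune_r2 LD pruning parameters
#'   (defaults 50, 5, 0.1).
#' @param window_bp LD score window (default 10 Mb).
#' @param n_blocks jackknife blocks (default 200).
#' @return list of class `trait_result` with elements `pair`, `h2_eas`,
#'   `h2_eur`, `xpop`, `decor_model`, `cfdr`, `classification`,
#'   `fourgroup`, `effects`, `divergence`, `grs`, and `log` (per-stage
#'   SNP counts).
#' @export
run_trait <- function(ss_eas, ss_eur, panel_eas, panel_eur,
                      trait_type = c("continuous", "binary"),
                      alpha = 0.05, null_p_threshold = 1e-4,
                      maf_min = 0.01, hwe_p = 1e-5,
                      prune_window = 50L, prune_step = 5L, prune_r2 = 0.1,
                      window_bp = 1e7, n_blocks = 200L) {
  trait_type <- match.arg(trait_type)
  log <- list(input_eas = nrow(ss_eas), input_eur = nrow(ss_eur))

  qc1 <- qc_filter(ss_eas, panel_eas, maf_min = maf_min)
  qc2 <- qc_filter(ss_eur, panel_eur, maf_min = maf_min)
  pair <- harmonize_pair(qc1, qc2)
  log$harmonized <- length(pair$snps)

  p1 <- subset_panel(panel_eas, pair$snps)
  p2 <- subset_panel(panel_eur, pair$snps)

  # LD-based estimation set: outside the MHC, common, in HWE
  ld_ok <- mhc_mask(p1$snp_meta) &
    hwe_pass(p1, hwe_p) & hwe_pass(p2, hwe_p) &
    compute_maf(p1) > maf_min & compute_maf(p2) > maf_min
  log$ld_estimation_set <- sum(ld_ok)
  snps_ld <- pair$snps[ld_ok]
  p1_ld <- subset_panel(p1, snps_ld)
  p2_ld <- subset_panel(p2, snps_ld)
  ld1 <- ld_scores(p1_ld, window_bp = window_bp)
  ld2 <- ld_scores(p2_ld, window_bp = window_bp)
  ldx <- cross_ld_scores(p1_ld, p2_ld, window_bp = window_bp)

  keep_ld <- pair$snps %in% snps_ld
  sub_pair <- subset_pair(pair, keep_ld)
  h2_eas <- estimate_h2(sub_pair$eas, ld1, n_blocks = n_blocks)
  h2_eur <- estimate_h2(sub_pair$eur, ld2, n_blocks = n_blocks)
  xpop <- tryCatch(
    trans_ethnic_rg(sub_pair, ld1, ld2, ldx, h2_eas, h2_eur,
                    n_blocks = n_blocks),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "xpop_estimate"))

  kept1 <- ld_prune(p1_ld, prune_window, prune_step, prune_r2)
  kept2 <- ld_prune(p2_ld, prune_window, prune_step, prune_r2)
  pruned <- snps_ld[snps_ld %in% union(kept1, kept2)]
  log$pruned_union <- length(pruned)
  cf_pair <- subset_pair(pair, pair$snps %in% pruned)

  model <- estimate_null_correlation(cf_pair, null_p_threshold)
  dz <- decorrelate(cf_pair, model)
  cfdr <- empirical_cfdr(dz$p1, dz$p2, snp_id = cf_pair$snps)
  cls <- classify_snps(cfdr, alpha = alpha)
  fg <- fit_four_group(dz$p1, dz$p2)

  eff <- effects_by_group(cf_pair, cls)

  p1_pr <- subset_panel(p1_ld, cf_pair$snps)
  p2_pr <- subset_panel(p2_ld, cf_pair$snps)
  fst_vec <- fst(p1_pr, p2_pr)
  i1 <- match(cf_pair$snps, ld1$snp_id); i2 <- match(cf_pair$snps, ld2$snp_id)
  div <- divergence_table(cls,
                          ld1[i1, , drop = FALSE], ld2[i2, , drop = FALSE],
                          compute_maf(p1_pr), compute_maf(p2_pr), fst_vec)
  div_tests <- list(ldcv = group_kruskal(div$ldcv, div$group),
                    mafcv = group_kruskal(div$mafcv, div$group),
                    fst = group_kruskal(div$fst, div$group))

  grs <- grs_analysis(cls, cf_pair, p1_pr, p2_pr, trait_type = trait_type)

  structure(list(pair = pair, h2_eas = h2_eas, h2_eur = h2_eur,
                 xpop = xpop, decor_model = model, cfdr = cfdr,
                 classification = cls, fourgroup = fg, effects = eff,
                 divergence = div, divergence_tests = div_tests,
                 grs = grs, log = log),
            class = "trait_result")
}

# Restrict a harmonized pair to a logical mask over its SNPs.
subset_pair <- function(pair, keep) {
  structure(list(snps = pair$snps[keep],
                 eas = sumstat_table(as.data.frame(pair$eas)[keep, , drop = FALSE]),
                 eur = sumstat_table(as.data.frame(pair$eur)[keep, , drop = FALSE]),
                 flipped = pair$flipped[keep],
                 n_dropped_irreconcilable = pair$n_dropped_irreconcilable),
            class = "harmonized_pair")
}

# Per-group marginal correlations plus common-SNP slope and heterogeneity.
effects_by_group <- function(pair, cls) {
  lab <- cls$label
  by_group <- lapply(stats::setNames(nm = unique(lab)), function(g) {
    i <- which(lab == g)
    if (length(i) < 10L) return(NULL)
    magic_corr(pair$eas$beta[i], pair$eas$se[i],
               pair$eur$beta[i], pair$eur$se[i])
  })
  common <- which(lab == "common")
  slope <- het <- NULL
  if (length(common) >= 3L) {
    slope <- slope_no_intercept(pair$eas$beta[common], pair$eur$beta[common])
    het <- cochran_q(pair$eas$beta[common], pair$eas$se[common],
                     pair$eur$beta[common], pair$eur$se[common])
  }
  list(marginal_correlation = by_group, slope = slope, heterogeneity = het)
}

#' Bundled published trait estimates for 37 complex traits
#'
#' Heritability estimates (with standard errors), heritability-difference
#' P values and trans-ethnic genetic correlations (with standard errors
#' and P values against 1) for 37 complex traits analyzed in East Asian
#' and European GWAS, as reported in the published analysis this package
#' operationalizes. Six traits whose correlation estimate exceeded 1 have
#' missing `rho_g`. Used by the worked examples and the summary reports.
#'
#' @return data.frame with columns `trait`, `type`, `h2_eas`, `se_eas`,
#'   `h2_eur`, `se_eur`, `p_h2diff`, `rho_g`, `rho_se`, `p_rho`.
#' @export
trait_estimates <- function() {
  utils::read.delim(system.file("extdata", "eas_eur_trait_estimates.tsv",
                                package = "transarch"),
                    stringsAsFactors = FALSE)
}

#' Bundled published SNP-classification counts for 37 complex traits
#'
#' Per-trait counts of analyzed SNPs (`k`), population-specific
#' associations (`f10`, `f01`), shared associations (`f11`), the
#' four-group-model shared proportion (`pi11_pct`) and the adjusted LRT
#' P value, as reported in the published analysis.
#'
#' @return data.frame with columns `trait`, `k`, `f10`, `f01`, `f11`,
#'   `pi11_pct`, `p_lrt`.
#' @export
snp_classification_counts <- function() {
  utils::read.delim(system.file("extdata",
                                "eas_eur_snp_classification_counts.tsv",
                                package = "transarch"),
                    stringsAsFactors = FALSE)
}

#' Summary report over per-trait heritability and correlation estimates
#'
#' Given a table shaped like [trait_estimates()], computes the Pearson
#' correlation (with P) of the heritability estimates between the two
#' populations, the heritability-difference tests with
#' Benjamini-Hochberg adjustment and the count/fraction of significant
#' differences, the mean trans-ethnic correlation overall and by trait
#' type (estimates above 1 excluded, as missing), and the count of
#' correlations significantly below 1 at the per-test 0.05 level.
#'
#' @param df data.frame with columns `type`, `h2_eas`, `se_eas`,
#'   `h2_eur`, `se_eur`, `rho_g`, and `rho_se` and/or `p_rho`.
#' @param fdr_level level for the adjusted heritability-difference count
#'   (default 0.05).
#' @return list with `h2_correlation` (`r`, `p`), `h2_diff` (data.frame),
#'   `n_h2_diff_significant`, `frac_h2_diff_significant`, `rho_mean`,
#'   `rho_mean_by_type`, `n_rho_lt1`, `n_rho_available`.
#' @export
summarize_table1 <- function(df, fdr_level = 0.05) {
  if (nrow(df) < 2L) stop("summarize_table1: need at least 2 traits")
  h2cor <- if (stats::sd(df$h2_eas) == 0 || stats::sd(df$h2_eur) == 0) {
    list(r = NA_real_, p = NA_real_, reason = "degenerate (constant estimates)")
  } else {
    ct <- stats::cor.test(df$h2_eas, df$h2_eur)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  hd <- h2_diff_test(df$h2_eas, df$se_eas, df$h2_eur, df$se_eur)
  hd <- cbind(trait = df$trait, hd)
  nsig <- sum(hd$p_adjusted < fdr_level)
  rho <- df$rho_g
  rho[!is.na(rho) & abs(rho) > 1] <- NA  # unbounded estimates excluded
  p_rho <- if ("p_rho" %in% names(df)) df$p_rho else
    two_sided_p((rho - 1) / df$rho_se)
  by_type <- tapply(rho, df$type, mean, na.rm = TRUE)
  by_type[tapply(!is.na(rho), df$type, sum) == 0L] <- NA
  list(h2_correlation = h2cor,
       h2_diff = hd,
       n_h2_diff_significant = nsig,
       frac_h2_diff_significant = nsig / nrow(df),
       rho_mean = mean(rho, na.rm = TRUE),
       rho_mean_by_type = by_type,
       rho_sd_by_type = tapply(rho, df$type, stats::sd, na.rm = TRUE),
       n_rho_lt1 = sum(!is.na(rho) & p_rho < 0.05),
       n_rho_available = sum(!is.na(rho)))
}

#' Summary report over per-trait SNP-classification counts
#'
#' Given a table shaped like [snp_classification_counts()], computes the
#' mean shared proportion, its range with trait names, and (when sample
#' sizes are supplied) the correlations of discovery counts with sample
#' size and of shared discoveries with the sample-size coefficient of
#' variation.
#'
#' @param df data.frame with columns `trait`, `k`, `f10`, `f01`, `f11`,
#'   `pi11_pct`.
#' @param n1,n2 optional per-trait effective sample sizes.
#' @return list with `pi11_mean_pct`, `pi11_range`,
#'   `n_more_in_pop2` (traits with more associations in population 2)
#'   and, when sample sizes are given, `cor_n1_f1x`, `cor_n2_fx1`,
#'   `cor_ncv_f11`.
#' @export
summarize_table2 <- function(df, n1 = NULL, n2 = NULL) {
  if (nrow(df) < 1L) stop("summarize_table2: need at least 1 trait")
  out <- list(
    pi11_mean_pct = mean(df$pi11_pct),
    pi11_range = list(
      min = list(trait = df$trait[which.min(df$pi11_pct)],
                 value = min(df$pi11_pct)),
      max = list(trait = df$trait[which.max(df$pi11_pct)],
                 value = max(df$pi11_pct))),
    n_more_in_pop2 = sum(df$f01 + df$f11 > df$f10 + df$f11)
  )
  if (!is.null(n1) && !is.null(n2)) {
    out$cor_n1_f1x <- stats::cor(n1, df$f10 + df$f11)
    out$cor_n2_fx1 <- stats::cor(n2, df$f01 + df$f11)
    out$cor_ncv_f11 <- stats::cor(ncv(n1, n2), df$f11)
  }
  out
}
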