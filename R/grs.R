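#' Rescale a continuous-trait effect size from its Z statistic
#'
#' For cross-population comparability of continuous traits, effects are
#' put on a standardized scale:
#' `beta_new = z / sqrt(2 * maf * (1 - maf) * n + z^2)`. The result is
#' bounded in (-1, 1) and keeps the sign of `z`. Binary-trait effects are
#' used as-is.
#'
#' @param z signed test statistic (vectorized).
#' @param maf minor allele frequency in (0, 0.5].
#' @param n sample size (> 0).
#' @return rescaled effect size(s).
#' @export
rescale_beta <- function(z, maf, n) {
  if (any(maf <= 0 | maf > 0.5)) stop("rescale_beta: maf must lie in (0, 0.5]")
  if (any(n <= 0)) stop("rescale_beta: n must be positive")
  z / sqrt(2 * maf * (1 - maf) * n + z^2)
}

#' Genetic risk scores for a panel of individuals
#'
#' The score of an individual is the mean over the J used SNPs of dosage
#' times effect size: `GRS = sum_j G_j * beta_j / J`. SNPs absent from
#' the panel are dropped (and counted); missing dosages are mean-imputed
#' at twice the panel allele frequency.
#'
#' @param panel a [genotype_panel].
#' @param betas named numeric vector of per-SNP effects (names = SNP ids)
#'   aligned to the panel's counted (alt) allele.
#' @param snp_set SNP ids to use (default: all names of `betas`).
#' @return list with per-individual `scores`, `j` (SNPs used) and
#'   `n_dropped` (requested SNPs absent from the panel).
#' @export
compute_grs <- function(panel, betas, snp_set = names(betas)) {
  if (is.null(names(betas))) stop("compute_grs: betas must be named by SNP id")
  idx <- match(snp_set, panel$snp_meta$id)
  dropped <- sum(is.na(idx))
  use <- snp_set[!is.na(idx)]
  if (length(use) == 0L) stop("compute_grs: no usable SNPs in the panel")
  d <- panel$dosage[, match(use, panel$snp_meta$id), drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    nai <- which(is.na(d), arr.ind = TRUE)
    d[nai] <- mu[nai[, 2L]]
  }
  b <- betas[use]
  list(scores = as.numeric(d %*% b) / length(use),
       j = length(use), n_dropped = dropped)
}

#' Overall and partial genetic risk score analysis
#'
#' Builds three genetic risk scores per trait from the four-way SNP
#' classification: `overall` (all SNPs associated in a population:
#' f10+f11 for the first population, f01+f11 for the second),
#' `common_partial` (shared SNPs, f11) and `specific_partial`
#' (population-specific SNPs, f10 / f01). Each population's reference
#' panel is scored with that population's own effect estimates
#' (rescaled via [rescale_beta()] for continuous traits, original
#' effects for binary traits), and the two score distributions are
#' compared with Welch's two-sample t test (or Wilcoxon). The sign of
#' the mean difference labels which population carries the higher
#' genetic effect.
#'
#' @param class a [classify_snps()] result.
#' @param pair the [harmonize_pair()] the classification came from.
#' @param panel_eas,panel_eur reference [genotype_panel]s.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param comparison `"welch"` (default) or `"wilcoxon"`.
#' @return list of class `grs_result` with one entry per score type,
#'   each holding `scores_eas`, `scores_eur`, `j_eas`, `j_eur`,
#'   `statistic`, `p`, `direction` (`"EAS-higher"`, `"EUR-higher"` or
#'   `"n.s."` at 0.05).
#' @export
grs_analysis <- function(class, pair, panel_eas, panel_eur,
                         trait_type = c("continuous", "binary"),
                         comparison = c("welch", "wilcoxon")) {
  trait_type <- match.arg(trait_type)
  comparison <- match.arg(comparison)
  eff <- function(ss) {
    if (trait_type == "binary") stats::setNames(ss$beta, ss$snp_id)
    else stats::setNames(rescale_beta(ss$z, ss$maf, ss$n), ss$snp_id)
  }
  b_eas <- eff(pair$eas); b_eur <- eff(pair$eur)
  lab <- stats::setNames(class$label, class$snp_id)
  sets <- list(
    overall = list(eas = names(lab)[lab %in% c("eas_specific", "common")],
                   eur = names(lab)[lab %in% c("eur_specific", "common")]),
    common_partial = list(eas = names(lab)[lab == "common"],
                          eur = names(lab)[lab == "common"]),
    specific_partial = list(eas = names(lab)[lab == "eas_specific"],
                            eur = names(lab)[lab == "eur_specific"])
  )
  out <- list()
  for (type in names(sets)) {
    s <- sets[[type]]
    if (length(s$eas) == 0L || length(s$eur) == 0L) {
      warning("grs_analysis: no SNPs for '", type, "'; skipped")
      next
    }
    g1 <- compute_grs(panel_eas, b_eas, s$eas)
    g2 <- compute_grs(panel_eur, b_eur, s$eur)
    if (comparison == "welch") {
      ht <- stats::t.test(g1$scores, g2$scores)
    } else {
      ht <- stats::wilcox.test(g1$scores, g2$scores, exact = FALSE)
    }
    delta <- mean(g1$scores) - mean(g2$scores)
    out[[type]] <- list(
      scores_eas = g1$scores, scores_eur = g2$scores,
      j_eas = g1$j, j_eur = g2$j,
      n_dropped = g1$n_dropped + g2$n_dropped,
      statistic = unname(ht$statistic), p = ht$p.value,
      direction = if (ht$p.value >= 0.05) "n.s."
                  else if (delta > 0) "EAS-higher" else "EUR-higher")
  }
  class(out) <- "grs_result"
  out
}

#' @export
print.grs_result <- function(x, ...) {
  for (type in names(x)) {
    g <- x[[type]]
    cat(sprintf("%-17s J = %d/%d, P = %.3g, %s\n",
                type, g$j_eas, g$j_eur, g$p, g$direction))
  }
  invisible(x)
}
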