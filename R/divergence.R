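#' Kruskal-Wallis comparison of a divergence statistic across SNP groups
#'
#' Compares a per-SNP statistic (LDCV, MAFCV or Fst) across the populated
#' SNP groups with the rank-based Kruskal-Wallis test (average-rank tie
#' correction, degrees of freedom = populated groups - 1). With a single
#' populated group the P value is missing; with all values identical the
#' statistic is 0 and P is 1 by convention.
#'
#' @param values per-SNP statistic (NA allowed, dropped).
#' @param groups group labels aligned with `values`.
#' @return list with `h`, `df`, `p`, `n_groups`.
#' @export
group_kruskal <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups[keep]))
  g <- nlevels(droplevels(groups))
  if (g < 2L) return(list(h = NA_real_, df = NA_integer_, p = NA_real_,
                          n_groups = g))
  if (length(unique(values)) == 1L) {
    return(list(h = 0, df = g - 1L, p = 1, n_groups = g))
  }
  kt <- stats::kruskal.test(values, groups)
  list(h = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n_groups = g)
}

#' Paired comparison of per-group means across traits
#'
#' Given a traits x groups matrix of per-trait group means (for example
#' the mean LDCV of each SNP group for every trait), runs a paired t test
#' between every pair of group columns across traits, alongside the
#' column means and across-trait standard deviations. A constant
#' difference (zero variance) is the exact-shift limit: P is reported as
#' 0 when the shift is non-zero and 1 otherwise, with `degenerate = TRUE`.
#'
#' @param group_means numeric matrix or data.frame, traits in rows,
#'   groups in columns (column names label the groups).
#' @param method `"t"` (paired t, default) or `"wilcoxon"` (paired
#'   signed-rank).
#' @return list with `pairs` (data.frame of pairwise results) and
#'   `summary` (per-group mean and sd across traits).
#' @export
paired_group_means <- function(group_means, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  gm <- as.matrix(group_means)
  if (nrow(gm) < 5L) {
    warning("paired_group_means: fewer than 5 traits; P values are unstable")
  }
  if (is.null(colnames(gm))) colnames(gm) <- paste0("g", seq_len(ncol(gm)))
  cols <- colnames(gm)
  res <- list()
  for (i in seq_len(ncol(gm) - 1L)) {
    for (j in (i + 1L):ncol(gm)) {
      d <- gm[, i] - gm[, j]
      d <- d[!is.na(d)]
      degenerate <- stats::sd(d) < 1e-12 * max(1, abs(mean(d)))
      if (degenerate) {
        p <- if (all(d == 0)) 1 else 0
        stat <- NA_real_
      } else if (method == "t") {
        tt <- stats::t.test(d)
        p <- tt$p.value; stat <- unname(tt$statistic)
      } else {
        wt <- stats::wilcox.test(d, exact = FALSE)
        p <- wt$p.value; stat <- unname(wt$statistic)
      }
      res[[length(res) + 1L]] <- data.frame(
        group_a = cols[i], group_b = cols[j],
        mean_a = mean(gm[, i], na.rm = TRUE),
        mean_b = mean(gm[, j], na.rm = TRUE),
        statistic = stat, p = p, degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
  }
  list(pairs = do.call(rbind, res),
       summary = data.frame(group = cols,
                            mean = colMeans(gm, na.rm = TRUE),
                            sd = apply(gm, 2L, stats::sd, na.rm = TRUE),
                            stringsAsFactors = FALSE))
}

#' Assemble the per-SNP divergence table
#'
#' Joins the four-way classification with the two populations' LD scores,
#' minor allele frequencies and per-SNP Fst into one table of
#' cross-population divergence statistics: LDCV and MAFCV (two-value
#' coefficients of variation) and Fst (missing values propagated).
#' Also reports the correlation of Fst with LDCV and with MAFCV, to check
#' whether LD/MAF divergence is confounded by allele-frequency
#' differentiation.
#'
#' @param class a [classify_snps()] result.
#' @param ld1,ld2 LD score tables (`snp_id`, `ell`) covering the SNPs.
#' @param maf1,maf2 per-SNP minor allele frequencies aligned with
#'   `class$snp_id`.
#' @param fst per-SNP Fst aligned with `class$snp_id`.
#' @return data.frame of class `divergence_table` with `snp_id`, `group`,
#'   `ldcv`, `mafcv`, `fst`; attributes `fst_ldcv_cor` and
#'   `fst_mafcv_cor` hold `cor.test` summaries.
#' @export
divergence_table <- function(class, ld1, ld2, maf1, maf2, fst) {
  snps <- class$snp_id
  n <- length(snps)
  if (length(maf1) != n || length(maf2) != n || length(fst) != n) {
    stop("divergence_table: maf and fst vectors must align with the classification")
  }
  i1 <- match(snps, ld1$snp_id); i2 <- match(snps, ld2$snp_id)
  if (anyNA(i1) || anyNA(i2)) {
    stop("divergence_table: LD score tables must cover all classified SNPs")
  }
  out <- data.frame(
    snp_id = snps, group = class$label,
    ldcv = two_value_cv(pmax(ld1$ell[i1], 0), pmax(ld2$ell[i2], 0)),
    mafcv = two_value_cv(maf1, maf2),
    fst = fst, stringsAsFactors = FALSE)
  ct <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(list(r = NA_real_, p = NA_real_))
    }
    h <- stats::cor.test(x[ok], y[ok])
    list(r = unname(h$estimate), p = h$p.value)
  }
  attr(out, "fst_ldcv_cor") <- ct(out$fst, out$ldcv)
  attr(out, "fst_mafcv_cor") <- ct(out$fst, out$mafcv)
  class(out) <- c("divergence_table", "data.frame")
  out
}
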