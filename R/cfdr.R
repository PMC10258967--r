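#' Estimate the null correlation of paired Z statistics
#'
#' Phenotypic and technical correlation between two GWAS of the same
#' trait inflates the joint statistics even for null SNPs. The
#' correlation is estimated as the Pearson correlation of the paired Z
#' statistics restricted to jointly null SNPs (both P above
#' `null_p_threshold`), and the whitening transform is the symmetric
#' inverse square root of the implied 2x2 correlation matrix — the unique
#' decorrelating transform closest to the identity, so it perturbs the
#' original statistics least.
#'
#' @param pair a [harmonize_pair()] result.
#' @param null_p_threshold P-value threshold defining null SNPs
#'   (default `1e-4`).
#' @return list of class `decorrelation_model` with `r_null` and the 2x2
#'   `transform` matrix.
#' @export
estimate_null_correlation <- function(pair, null_p_threshold = 1e-4) {
  nullset <- pair$eas$p > null_p_threshold & pair$eur$p > null_p_threshold
  if (sum(nullset) < 100L) {
    stop("estimate_null_correlation: only ", sum(nullset),
         " jointly null SNPs; loosen null_p_threshold")
  }
  r <- stats::cor(pair$eas$z[nullset], pair$eur$z[nullset])
  structure(list(r_null = r, transform = whitening_matrix(r),
                 n_null = sum(nullset)),
            class = "decorrelation_model")
}

#' Symmetric inverse square root of a 2x2 equicorrelation matrix
#'
#' @param r off-diagonal correlation, `|r| < 1`.
#' @return 2x2 matrix `W` with `W %*% C %*% t(W) = I` for
#'   `C = matrix(c(1, r, r, 1), 2)`.
#' @export
whitening_matrix <- function(r) {
  if (abs(r) >= 1) stop("whitening_matrix: |r| must be < 1")
  a <- 1 / sqrt(1 + r)  # eigenvalue 1+r, eigenvector (1,1)/sqrt(2)
  b <- 1 / sqrt(1 - r)
  matrix(c((a + b) / 2, (a - b) / 2, (a - b) / 2, (a + b) / 2), 2L, 2L)
}

#' Decorrelate paired Z statistics and recompute P values
#'
#' Multiplies each SNP's `(z1, z2)` by the model's whitening matrix and
#' recomputes two-sided normal-tail P values from the transformed Z.
#'
#' @param pair a [harmonize_pair()] result.
#' @param model a [estimate_null_correlation()] result.
#' @return list with `z1`, `z2`, `p1`, `p2` and the `snp_id` vector.
#' @export
decorrelate <- function(pair, model) {
  zz <- cbind(pair$eas$z, pair$eur$z) %*% model$transform
  list(snp_id = pair$snps,
       z1 = zz[, 1L], z2 = zz[, 2L],
       p1 = two_sided_p(zz[, 1L]), p2 = two_sided_p(zz[, 2L]))
}

# Fenwick (binary indexed) tree counts of {j : p1_j <= p1_i, p2_j <= p2_i},
# including i itself. O(n log n).
dominance_counts <- function(p1, p2) {
  n <- length(p1)
  r2 <- match(p2, sort(unique(p2)))           # ordinal of p2, ties share
  k <- max(r2)
  tree <- integer(k)
  out <- integer(n)
  ord <- order(p1)
  i <- 1L
  while (i <= n) {
    # group of tied p1 values: insert all, then query all
    j <- i
    while (j < n && p1[ord[j + 1L]] == p1[ord[i]]) j <- j + 1L
    for (t in i:j) {
      pos <- r2[ord[t]]
      while (pos <= k) {
        tree[pos] <- tree[pos] + 1L
        pos <- pos + bitwAnd(pos, -pos)
      }
    }
    for (t in i:j) {
      pos <- r2[ord[t]]
      s <- 0L
      while (pos > 0L) {
        s <- s + tree[pos]
        pos <- pos - bitwAnd(pos, -pos)
      }
      out[ord[t]] <- s
    }
    i <- j + 1L
  }
  out
}

#' Empirical conditional and conjunction FDR
#'
#' For each SNP i, the conditional FDR of population 1 given population 2
#' is estimated with the conservative empirical-Bayes ratio
#' `cfdr_1g2(i) = p1_i * #\{j: p2_j <= p2_i\} / #\{j: p1_j <= p1_i and
#' p2_j <= p2_i\}` (the null proportion is conservatively taken as 1),
#' clamped to `[0, 1]`; `cfdr_2g1` symmetrically; and the conjunction FDR
#' is `ccfdr = max(cfdr_1g2, cfdr_2g1)`. Ties are handled inclusively.
#' Inputs should come from approximately independent (LD-pruned,
#' decorrelated) SNPs.
#'
#' @param p1,p2 aligned P-value vectors in (0, 1].
#' @param snp_id optional SNP identifiers.
#' @return data.frame of class `cfdr_table` with `snp_id`, `p1`, `p2`,
#'   `cfdr_1g2`, `cfdr_2g1`, `ccfdr`.
#' @export
empirical_cfdr <- function(p1, p2, snp_id = NULL) {
  n <- length(p1)
  if (n == 0L || length(p2) != n) {
    stop("empirical_cfdr: p1 and p2 must be non-empty and aligned")
  }
  if (any(p1 <= 0 | p1 > 1 | p2 <= 0 | p2 > 1)) {
    stop("empirical_cfdr: P values must lie in (0, 1]")
  }
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(n))
  n1le <- rank(p1, ties.method = "max")
  n2le <- rank(p2, ties.method = "max")
  both <- dominance_counts(p1, p2)
  out <- data.frame(
    snp_id = snp_id, p1 = p1, p2 = p2,
    cfdr_1g2 = pmin(1, p1 * n2le / both),
    cfdr_2g1 = pmin(1, p2 * n1le / both),
    stringsAsFactors = FALSE
  )
  out$ccfdr <- pmax(out$cfdr_1g2, out$cfdr_2g1)
  class(out) <- c("cfdr_table", "data.frame")
  out
}

#' Four-way SNP classification from conditional FDRs
#'
#' A SNP is population-common when `ccfdr < alpha` (associated in both
#' populations), population-1-specific when only `cfdr_1g2 < alpha`,
#' population-2-specific when only `cfdr_2g1 < alpha`, and null
#' otherwise.
#'
#' @param table a [empirical_cfdr()] result.
#' @param alpha significance level in (0, 1) (default 0.05).
#' @return list of class `snp_classification` with per-SNP `label`
#'   (`"null"`, `"eas_specific"`, `"eur_specific"`, `"common"`) and the
#'   counts `k`, `f10`, `f01`, `f11`.
#' @export
classify_snps <- function(table, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("classify_snps: alpha must lie in (0, 1)")
  }
  sig1 <- table$cfdr_1g2 < alpha
  sig2 <- table$cfdr_2g1 < alpha
  label <- ifelse(sig1 & sig2, "common",
                  ifelse(sig1, "eas_specific",
                         ifelse(sig2, "eur_specific", "null")))
  structure(list(snp_id = table$snp_id, label = label,
                 k = nrow(table),
                 f10 = sum(label == "eas_specific"),
                 f01 = sum(label == "eur_specific"),
                 f11 = sum(label == "common"),
                 alpha = alpha),
            class = "snp_classification")
}

#' @export
print.snp_classification <- function(x, ...) {
  cat(sprintf("snp_classification (alpha = %g): k = %d, f10 = %d, f01 = %d, f11 = %d\n",
              x$alpha, x$k, x$f10, x$f01, x$f11))
  invisible(x)
}

#' Naive minimum-P conjunction baseline
#'
#' The natural naive rule for calling a SNP associated in both
#' populations: Benjamini-Hochberg-adjust the per-SNP `max(p1, p2)` and
#' call SNPs with adjusted value below `alpha`. This is a baseline
#' definition for benchmarking the conjunction FDR, not an established
#' method.
#'
#' @param p1,p2 aligned P-value vectors.
#' @param alpha level (default 0.05).
#' @return logical vector, `TRUE` for SNPs called shared.
#' @export
minp_baseline <- function(p1, p2, alpha = 0.05) {
  stats::p.adjust(pmax(p1, p2), method = "BH") < alpha
}
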