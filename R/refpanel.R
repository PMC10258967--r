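#' Construct a reference genotype panel
#'
#' A `genotype_panel` holds a samples x SNPs dosage matrix coded 0/1/2
#' (copies of the alternative allele; `NA` for missing calls) together
#' with per-SNP metadata. Panels back LD scores, LD pruning, reference
#' MAF, Hardy-Weinberg filtering, Fst and genetic risk scores.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns.
#' @param snp_meta data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` (one row per SNP, same order as `dosage` columns).
#' @param sample_ids optional character vector of sample identifiers.
#' @return list of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, snp_meta, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(snp_meta)) {
    stop("genotype_panel: dosage has ", ncol(dosage),
         " SNPs but snp_meta has ", nrow(snp_meta), " rows")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosage)))
  if (length(sample_ids) != nrow(dosage)) {
    stop("genotype_panel: sample_ids length does not match dosage rows")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) > 0L && !all(bad %in% c(0, 1, 2))) {
    stop("genotype_panel: dosages must be 0, 1, 2 or NA")
  }
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(snp_meta))
  if (length(miss) > 0L) {
    stop("genotype_panel: snp_meta missing column(s): ",
         paste(miss, collapse = ", "))
  }
  colnames(dosage) <- snp_meta$id
  structure(list(sample_ids = sample_ids,
                 snp_meta = as.data.frame(snp_meta, stringsAsFactors = FALSE),
                 dosage = dosage),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "samples x",
      nrow(x$snp_meta), "SNPs\n")
  invisible(x)
}

#' Subset a genotype panel to a set of SNP ids (in the given order)
#'
#' @param panel a [genotype_panel].
#' @param snp_ids SNP identifiers to keep, in the desired order.
#' @return a [genotype_panel].
#' @export
subset_panel <- function(panel, snp_ids) {
  idx <- match(snp_ids, panel$snp_meta$id)
  if (anyNA(idx)) {
    stop("subset_panel: ", sum(is.na(idx)), " SNP id(s) absent from panel")
  }
  genotype_panel(panel$dosage[, idx, drop = FALSE],
                 panel$snp_meta[idx, , drop = FALSE],
                 panel$sample_ids)
}

#' Read a reference panel from VCF
#'
#' GT fields are converted to alternative-allele dosages; multi-allelic
#' records are dropped.
#'
#' @param path path to a VCF file (optionally gzipped).
#' @return a [genotype_panel].
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    out[g %in% c("1/1", "1|1")] <- 2
    out
  }
  dos <- t(apply(gt, 1L, count_alt))  # SNPs x samples
  meta <- data.frame(id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  genotype_panel(t(dos), meta, colnames(gt))
}

#' Write a reference panel as an uncompressed VCF
#'
#' @param panel a [genotype_panel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  meta <- panel$snp_meta
  gt_code <- c("0/0", "0/1", "1/1")
  gmat <- matrix("./.", nrow = nrow(meta), ncol = length(panel$sample_ids))
  obs <- !is.na(t(panel$dosage))
  gmat[obs] <- gt_code[t(panel$dosage)[obs] + 1L]
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t"),
    paste(meta$chrom, meta$pos, meta$id, meta$ref, meta$alt, ".", "PASS",
          ".", "GT", apply(gmat, 1L, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Minor allele frequency from a genotype panel
#'
#' Alternative-allele frequencies over non-missing calls, folded at 0.5.
#' SNPs with no non-missing call are returned as `NA`.
#'
#' @param panel a [genotype_panel].
#' @return numeric vector of per-SNP MAF in `[0, 0.5]`.
#' @export
compute_maf <- function(panel) {
  p <- colMeans(panel$dosage, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Hardy-Weinberg equilibrium filter
#'
#' One-degree-of-freedom chi-squared goodness-of-fit test of the three
#' genotype counts against Hardy-Weinberg proportions. Monomorphic SNPs
#' pass by convention (the test is undefined; P is treated as 1).
#'
#' @param panel a [genotype_panel].
#' @param threshold P-value threshold; SNPs with P above it pass
#'   (default `1e-5`).
#' @return logical vector, `TRUE` where the SNP passes.
#' @export
hwe_pass <- function(panel, threshold = 1e-5) {
  d <- panel$dosage
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  mono <- n == 0 | p <= 0 | p >= 1
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  chi2 <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  pval <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  pval[mono] <- 1
  pval > threshold
}

# Standardize dosage columns; missing calls imputed at the SNP mean.
# Monomorphic columns come back as all-zero.
standardize_dosage <- function(d) {
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(d)) {
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2L]]
  }
  d <- sweep(d, 2L, mu, "-")
  s <- sqrt(colSums(d^2) / (nrow(d) - 1L))
  s[s == 0] <- Inf
  sweep(d, 2L, s, "/")
}

#' Within-population LD scores
#'
#' For each SNP j, the LD score is the sum over SNPs k on the same
#' chromosome within `window_bp` of `pos_j` of the bias-adjusted squared
#' correlation `r2 - (1 - r2) / (n - 2)`, including the self term (1).
#' SNPs must be sorted by chromosome and position; the contributing set
#' should already be MAF/HWE filtered.
#'
#' @param panel a [genotype_panel], SNPs position-sorted.
#' @param window_bp window half-width in base pairs (default 10 Mb).
#' @return data.frame with `snp_id` and `ell`.
#' @export
ld_scores <- function(panel, window_bp = 1e7) {
  if (window_bp <= 0) stop("ld_scores: window_bp must be positive")
  meta <- panel$snp_meta
  n <- length(panel$sample_ids)
  x <- standardize_dosage(panel$dosage)
  ell <- numeric(nrow(meta))
  for (chr in unique(meta$chrom)) {
    j <- which(meta$chrom == chr)
    pos <- meta$pos[j]
    if (is.unsorted(pos)) stop("ld_scores: SNPs not position-sorted on ", chr)
    xc <- x[, j, drop = FALSE]
    m <- length(j)
    chunk <- 512L
    for (s in seq(1L, m, by = chunk)) {
      e <- min(s + chunk - 1L, m)
      lo <- findInterval(pos[s:e] - window_bp - 1L, pos) + 1L
      hi <- findInterval(pos[s:e] + window_bp, pos)
      rng <- min(lo):max(hi)
      r <- crossprod(xc[, s:e, drop = FALSE], xc[, rng, drop = FALSE]) / (n - 1L)
      r2 <- r^2
      r2adj <- r2 - (1 - r2) / (n - 2L)
      for (i in seq_len(e - s + 1L)) {
        win <- (lo[i]:hi[i]) - rng[1L] + 1L
        ell[j[s + i - 1L]] <- sum(r2adj[i, win])
      }
    }
  }
  data.frame(snp_id = meta$id, ell = ell, stringsAsFactors = FALSE)
}

#' Cross-population LD scores
#'
#' For SNPs shared between two panels (identical ids in identical order),
#' the cross-population LD score of SNP j is the windowed sum of the
#' products of the signed correlations `r1_jk * r2_jk` estimated in each
#' panel, including the self term (1). No small-sample adjustment is
#' applied; scores may be negative.
#'
#' @param panel1,panel2 [genotype_panel]s restricted to the shared SNPs.
#' @param window_bp window half-width in base pairs (default 10 Mb).
#' @return data.frame with `snp_id` and `ell_x`.
#' @export
cross_ld_scores <- function(panel1, panel2, window_bp = 1e7) {
  if (!identical(panel1$snp_meta$id, panel2$snp_meta$id)) {
    stop("cross_ld_scores: panels must hold identical SNPs in identical order")
  }
  meta <- panel1$snp_meta
  n1 <- length(panel1$sample_ids); n2 <- length(panel2$sample_ids)
  x1 <- standardize_dosage(panel1$dosage)
  x2 <- standardize_dosage(panel2$dosage)
  ellx <- numeric(nrow(meta))
  for (chr in unique(meta$chrom)) {
    j <- which(meta$chrom == chr)
    pos <- meta$pos[j]
    x1c <- x1[, j, drop = FALSE]; x2c <- x2[, j, drop = FALSE]
    m <- length(j)
    chunk <- 512L
    for (s in seq(1L, m, by = chunk)) {
      e <- min(s + chunk - 1L, m)
      lo <- findInterval(pos[s:e] - window_bp - 1L, pos) + 1L
      hi <- findInterval(pos[s:e] + window_bp, pos)
      rng <- min(lo):max(hi)
      r1 <- crossprod(x1c[, s:e, drop = FALSE], x1c[, rng, drop = FALSE]) / (n1 - 1L)
      r2 <- crossprod(x2c[, s:e, drop = FALSE], x2c[, rng, drop = FALSE]) / (n2 - 1L)
      pr <- r1 * r2
      for (i in seq_len(e - s + 1L)) {
        win <- (lo[i]:hi[i]) - rng[1L] + 1L
        self <- (s + i - 1L) - rng[1L] + 1L
        v <- sum(pr[i, win])
        # force the self term to exactly 1 (each panel's self correlation is 1)
        ellx[j[s + i - 1L]] <- v - pr[i, self] + 1
      }
    }
  }
  data.frame(snp_id = meta$id, ell_x = ellx, stringsAsFactors = FALSE)
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window of `window_snps` position-sorted SNPs,
#' while any kept pair exceeds the squared-correlation threshold, the
#' member of the worst pair with the lower MAF is removed; the window
#' then slides by `step` SNPs.
#'
#' @param panel a [genotype_panel], SNPs position-sorted.
#' @param window_snps window width in SNPs (default 50).
#' @param step slide in SNPs (default 5).
#' @param r2_threshold squared-correlation threshold (default 0.1).
#' @return character vector of kept SNP ids.
#' @export
ld_prune <- function(panel, window_snps = 50L, step = 5L, r2_threshold = 0.1) {
  meta <- panel$snp_meta
  maf <- compute_maf(panel)
  x <- standardize_dosage(panel$dosage)
  n <- nrow(x)
  keep <- rep(TRUE, nrow(meta))
  for (chr in unique(meta$chrom)) {
    j <- which(meta$chrom == chr)
    if (is.unsorted(meta$pos[j])) stop("ld_prune: SNPs not position-sorted on ", chr)
    m <- length(j)
    for (s in seq(1L, max(1L, m - 1L), by = step)) {
      e <- min(s + window_snps - 1L, m)
      idx <- j[s:e]
      idx <- idx[keep[idx]]
      if (length(idx) < 2L) next
      r2 <- (crossprod(x[, idx, drop = FALSE]) / (n - 1L))^2
      diag(r2) <- 0
      while (TRUE) {
        w <- which.max(r2)
        if (r2[w] <= r2_threshold) break
        ij <- arrayInd(w, dim(r2))
        pick <- if (maf[idx[ij[1L]]] <= maf[idx[ij[2L]]]) ij[1L] else ij[2L]
        keep[idx[pick]] <- FALSE
        r2[pick, ] <- 0
        r2[, pick] <- 0
      }
      if (e == m) break
    }
  }
  meta$id[keep]
}

#' Per-SNP Fst between two populations
#'
#' Weir-Cockerham (two-population, diploid; the default) or Hudson
#' estimators of Wright's fixation index. Panels must hold the same SNPs
#' with aligned alleles. Negative estimates are reported as-is; SNPs
#' monomorphic for the same allele in both panels are `NA`.
#'
#' @param panel1,panel2 [genotype_panel]s on identical SNP sets.
#' @param estimator `"weir_cockerham"` or `"hudson"`.
#' @return numeric vector of per-SNP Fst.
#' @export
fst <- function(panel1, panel2, estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  if (!identical(panel1$snp_meta$id, panel2$snp_meta$id)) {
    stop("fst: panels must hold identical SNPs in identical order")
  }
  d1 <- panel1$dosage; d2 <- panel2$dosage
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  undef <- (p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1)
  out <- if (estimator == "hudson") {
    fst_hudson(p1, p2, 2 * n1, 2 * n2)
  } else {
    h1 <- colMeans(d1 == 1, na.rm = TRUE)
    h2 <- colMeans(d2 == 1, na.rm = TRUE)
    fst_weir_cockerham(p1, p2, n1, n2, h1, h2)
  }
  out[undef] <- NA_real_
  out
}

# Weir & Cockerham (1984) theta-hat for r = 2 populations, diploid.
fst_weir_cockerham <- function(p1, p2, n1, n2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  out <- a / denom
  out[denom == 0] <- NA_real_
  out
}

# Hudson estimator with haploid-equivalent allele counts m1, m2.
fst_hudson <- function(p1, p2, m1, m2) {
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (m1 - 1) -
    p2 * (1 - p2) / (m2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Major histocompatibility complex mask
#'
#' `FALSE` (excluded) exactly for SNPs on chromosome 6 between 28.5 and
#' 33.5 Mb inclusive, the extended MHC region whose long-range LD is
#' poorly captured by small reference panels.
#'
#' @param snp_meta data.frame with `chrom` and `pos` columns (a
#'   [genotype_panel]'s `snp_meta`, or any table with those columns).
#' @return logical vector, `TRUE` where the SNP is kept.
#' @export
mhc_mask <- function(snp_meta) {
  chrom <- sub("^chr", "", as.character(snp_meta$chrom))
  !(chrom == "6" & snp_meta$pos >= 28.5e6 & snp_meta$pos <= 33.5e6)
}
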