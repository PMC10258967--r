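# Shared helpers: tiny hand-built tables and panels used across tests.

std_dialect <- list(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                    effect_allele = "effect_allele",
                    other_allele = "other_allele",
                    beta = "beta", se = "se", z = "z", p = "p",
                    n = "n", maf = "maf")

# sumstat_table from minimal arguments
mk_ss <- function(snp_id, beta, se, effect = "A", other = "G",
                  chrom = "1", pos = seq_along(snp_id) * 1000,
                  n = 10000, maf = 0.25, ...) {
  sumstat_table(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                           effect_allele = effect, other_allele = other,
                           beta = beta, se = se, n = n, maf = maf, ...,
                           stringsAsFactors = FALSE))
}

# genotype_panel from a dosage matrix (samples x SNPs)
mk_panel <- function(dosage, ids = NULL, chrom = "1",
                     pos = NULL, ref = "A", alt = "G") {
  m <- ncol(dosage)
  if (is.null(ids)) ids <- sprintf("rs%d", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m) * 1000
  genotype_panel(dosage,
                 data.frame(id = ids, chrom = chrom, pos = pos,
                            ref = ref, alt = alt, stringsAsFactors = FALSE))
}

# harmonized pair directly from two aligned sumstat tables
mk_pair <- function(ss1, ss2) {
  structure(list(snps = ss1$snp_id, eas = ss1, eur = ss2,
                 flipped = rep(FALSE, nrow(ss1)),
                 n_dropped_irreconcilable = 0L),
            class = "harmonized_pair")
}

# flat LD-score tables for LD-free summary statistics
flat_ld <- function(snp_id) data.frame(snp_id = snp_id, ell = rep(1, length(snp_id)))
flat_ldx <- function(snp_id) data.frame(snp_id = snp_id, ell_x = rep(1, length(snp_id)))

# draw paired p-values from the four-group uniform/Beta mixture
draw_four_group <- function(n, pi, a1, a2, seed) {
  set.seed(seed)
  g <- sample(1:4, n, TRUE, pi)
  p1 <- ifelse(g %in% c(2, 4), stats::rbeta(n, a1, 1), stats::runif(n))
  p2 <- ifelse(g %in% c(3, 4), stats::rbeta(n, a2, 1), stats::runif(n))
  list(p1 = pmax(p1, 1e-300), p2 = pmax(p2, 1e-300), group = g)
}
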