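#' Configuration for the two-population GWAS simulator
#'
#' Defines the study conditions the generator emulates: two populations
#' with Balding-Nichols-differentiated allele frequencies at a target
#' Fst, blockwise LD, a four-group causal architecture (null /
#' population-1-specific / population-2-specific / shared) with effect
#' correlation `rho_shared` among shared causals, per-population
#' heritabilities, and marginal GWAS summary statistics at the given
#' sample sizes. Defaults describe a well-powered trait pair with the
#' asymmetric sample sizes typical of EAS vs EUR GWAS and
#' pruned-equivalent (independent) SNPs; set `ld_rho > 0` for blockwise
#' LD.
#'
#' @param m SNP count.
#' @param n1,n2 GWAS sample sizes in the two populations.
#' @param n_ref reference-panel sizes (length 2; defaults 504 and 503,
#'   the EAS and EUR panel sizes of the 1000 Genomes Project).
#' @param fst Balding-Nichols differentiation parameter in `[0, 0.5)`.
#' @param ld_rho adjacent-SNP latent correlation within a block, in
#'   `[0, 1)`.
#' @param block_size SNPs per LD block.
#' @param pi four group proportions (null, pop1-specific, pop2-specific,
#'   shared), summing to 1.
#' @param rho_shared effect correlation among shared causal SNPs.
#' @param h2_1,h2_2 per-population SNP heritabilities.
#' @param shared_low_divergence place shared causal SNPs preferentially
#'   where allele-frequency (and, with LD, block-LD) divergence between
#'   the populations is low, emulating the conserved architecture of
#'   population-common associations (default `TRUE`).
#' @param seed integer seed; every stage derives its own named stream
#'   from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m = 50000L, n1 = 20000L, n2 = 100000L,
                       n_ref = c(504L, 503L), fst = 0.06,
                       ld_rho = 0, block_size = 10L,
                       pi = c(0.90, 0.04, 0.04, 0.02),
                       rho_shared = 0.8, h2_1 = 0.3, h2_2 = 0.3,
                       shared_low_divergence = TRUE,
                       seed = 1L) {
  stopifnot(m > 0, n1 > 0, n2 > 0, all(n_ref > 0), length(n_ref) == 2L,
            fst >= 0, fst < 0.5, ld_rho >= 0, ld_rho < 1,
            block_size >= 1L, length(pi) == 4L, all(pi >= 0),
            abs(sum(pi) - 1) < 1e-9, abs(rho_shared) <= 1,
            h2_1 >= 0, h2_2 >= 0)
  structure(list(m = as.integer(m), n1 = n1, n2 = n2,
                 n_ref = as.integer(n_ref), fst = fst,
                 ld_rho = ld_rho, block_size = as.integer(block_size),
                 pi = pi, rho_shared = rho_shared,
                 h2_1 = h2_1, h2_2 = h2_2,
                 shared_low_divergence = isTRUE(shared_low_divergence),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-block LD strengths for one population
#'
#' When `ld_rho > 0`, each LD block draws its own adjacent-SNP latent
#' correlation uniformly from `[0.3, 1] * ld_rho`, independently in the
#' two populations, so block LD — like real LD — varies along the genome
#' and differs between populations.
#'
#' @param config a [sim_config()].
#' @param population 1 or 2.
#' @return numeric vector of per-block adjacent correlations.
#' @export
block_ld_rho <- function(config, population = 1L) {
  n_blocks <- ceiling(config$m / config$block_size)
  if (config$ld_rho == 0) return(rep(0, n_blocks))
  with_preserved_seed(
    stage_seed(config, if (population == 1L) "ldblocks1" else "ldblocks2"),
    stats::runif(n_blocks, 0.3, 1) * config$ld_rho)
}

# Named per-stage seed streams so stages can be re-run independently.
stage_seed <- function(config, stage) {
  offsets <- c(freq = 11L, geno1 = 23L, geno2 = 37L, effects = 53L,
               gwas1 = 71L, gwas2 = 89L, pheno1 = 101L, pheno2 = 113L,
               ldblocks1 = 127L, ldblocks2 = 131L)
  if (!stage %in% names(offsets)) stop("unknown seed stream: ", stage)
  # double arithmetic: the product overflows 32-bit integers
  as.integer((as.numeric(config$seed) * 2654435 + offsets[[stage]]) %% 2147483647)
}

#' Simulate differentiated allele frequencies for two populations
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each population draws
#' its frequency from the Balding-Nichols Beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, resampling any draw outside
#' (0.01, 0.99). With `F = 0` both populations inherit the ancestral
#' frequency exactly.
#'
#' @param config a [sim_config()].
#' @return list with `p_anc`, `p1`, `p2`.
#' @export
simulate_frequencies <- function(config) {
  with_preserved_seed(stage_seed(config, "freq"), {
    m <- config$m
    p_anc <- stats::runif(m, 0.05, 0.95)
    if (config$fst == 0) {
      return(list(p_anc = p_anc, p1 = p_anc, p2 = p_anc))
    }
    f <- config$fst
    draw <- function(p) {
      out <- stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
      bad <- which(out <= 0.01 | out >= 0.99)
      while (length(bad) > 0L) {
        out[bad] <- stats::rbeta(length(bad), p[bad] * (1 - f) / f,
                                 (1 - p[bad]) * (1 - f) / f)
        bad <- bad[out[bad] <= 0.01 | out[bad] >= 0.99]
      }
      out
    }
    list(p_anc = p_anc, p1 = draw(p_anc), p2 = draw(p_anc))
  })
}

# AR(1) latent Gaussian matrix (n x m) restarting at block boundaries;
# rho may be a per-block vector.
ar1_latent <- function(n, m, rho, block_size) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (any(rho > 0) && m > 1L) {
    rho_b <- rep_len(rho, ceiling(m / block_size))
    for (j in 2L:m) {
      if ((j - 1L) %% block_size != 0L) {
        r <- rho_b[(j - 1L) %/% block_size + 1L]
        if (r > 0) z[, j] <- r * z[, j - 1L] + sqrt(1 - r^2) * z[, j]
      }
    }
  }
  z
}

sim_snp_meta <- function(m, spacing = 5000L) {
  data.frame(id = sprintf("rs%d", seq_len(m)), chrom = "1",
             pos = seq_len(m) * spacing, ref = "A", alt = "G",
             stringsAsFactors = FALSE)
}

#' Simulate a genotype panel at given allele frequencies
#'
#' Two latent haplotypes per individual follow a blockwise AR(1)
#' Gaussian copula with adjacent correlation `ld_rho`; each is
#' thresholded at its SNP's allele frequency, so genotypes are in exact
#' Hardy-Weinberg proportions with LD inside blocks and independence
#' between blocks.
#'
#' @param freqs alternative-allele frequency vector.
#' @param n number of diploid individuals.
#' @param config a [sim_config()] (supplies `ld_rho` and `block_size`).
#' @param seed stream seed (default derived from the config).
#' @param block_rho optional per-block adjacent correlations (see
#'   [block_ld_rho()]); defaults to the constant `ld_rho`.
#' @return a [genotype_panel].
#' @export
simulate_genotypes <- function(freqs, n, config,
                               seed = stage_seed(config, "geno1"),
                               block_rho = NULL) {
  m <- length(freqs)
  if (is.null(block_rho)) block_rho <- config$ld_rho
  with_preserved_seed(seed, {
    thr <- stats::qnorm(freqs)
    h1 <- sweep(ar1_latent(n, m, block_rho, config$block_size), 2L, thr, "<")
    h2 <- sweep(ar1_latent(n, m, block_rho, config$block_size), 2L, thr, "<")
    genotype_panel(h1 + h2, sim_snp_meta(m))
  })
}

#' Assign four-group causal architecture and true effect sizes
#'
#' Group labels are multinomial with the configured proportions. Shared
#' causal SNPs draw bivariate-normal standardized effects with
#' correlation `rho_shared`; population-specific causals draw univariate
#' normal effects. Each population's effects are rescaled so its total
#' standardized genetic variance equals its heritability exactly. The
#' realized genome-wide effect correlation
#' `sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2))` is recorded as
#' `rho_g_true`: note it is smaller than `rho_shared` whenever
#' population-specific causal groups are present.
#'
#' @param config a [sim_config()].
#' @param freqs optional [simulate_frequencies()] result; when supplied,
#'   per-allele effects are added alongside the standardized ones, and
#'   (with `shared_low_divergence`) shared causals are placed in
#'   low-divergence SNPs.
#' @param block_rho1,block_rho2 optional per-block LD strengths (see
#'   [block_ld_rho()]); with `shared_low_divergence`, shared causals
#'   also prefer blocks whose LD strength is similar across populations.
#' @return data.frame of class `simulation_truth` with `snp_id`,
#'   `group`, `beta1_std`, `beta2_std` (and `beta1`, `beta2` per-allele
#'   when `freqs` given); attributes `rho_g_true` and `config`.
#' @export
assign_effects <- function(config, freqs = NULL,
                           block_rho1 = NULL, block_rho2 = NULL) {
  with_preserved_seed(stage_seed(config, "effects"), {
    m <- config$m
    labels <- c("null", "eas_specific", "eur_specific", "common")
    for (try in 1:100) {
      group <- draw_groups(config, freqs, block_rho1, block_rho2)
      c1 <- group %in% c("eas_specific", "common")
      c2 <- group %in% c("eur_specific", "common")
      if ((config$h2_1 == 0 || any(c1)) && (config$h2_2 == 0 || any(c2))) break
      warning("assign_effects: no causal SNPs drawn; resampling groups")
    }
    b1 <- numeric(m); b2 <- numeric(m)
    b1[c1] <- stats::rnorm(sum(c1))
    shared <- group == "common"
    u <- stats::rnorm(sum(shared))
    b2[shared] <- config$rho_shared * b1[shared] +
      sqrt(1 - config$rho_shared^2) * u
    b2[group == "eur_specific"] <- stats::rnorm(sum(group == "eur_specific"))
    if (any(c1) && config$h2_1 > 0) {
      b1[c1] <- b1[c1] * sqrt(config$h2_1 / sum(b1[c1]^2))
    } else b1[] <- 0
    if (any(c2) && config$h2_2 > 0) {
      b2[c2] <- b2[c2] * sqrt(config$h2_2 / sum(b2[c2]^2))
    } else b2[] <- 0
    denom <- sqrt(sum(b1^2) * sum(b2^2))
    rho_true <- if (denom > 0) sum(b1 * b2) / denom else NA_real_
    out <- data.frame(snp_id = sim_snp_meta(m)$id, group = group,
                      beta1_std = b1, beta2_std = b2,
                      stringsAsFactors = FALSE)
    if (!is.null(freqs)) {
      out$beta1 <- b1 / sqrt(2 * freqs$p1 * (1 - freqs$p1))
      out$beta2 <- b2 / sqrt(2 * freqs$p2 * (1 - freqs$p2))
    }
    attr(out, "rho_g_true") <- rho_true
    attr(out, "config") <- config
    class(out) <- c("simulation_truth", "data.frame")
    out
  })
}

# Multinomial group counts; shared causals optionally drawn from the
# low-divergence half of SNPs (allele-frequency CV, plus block-LD
# dissimilarity when block LD strengths are available).
draw_groups <- function(config, freqs, block_rho1, block_rho2) {
  m <- config$m
  labels <- c("null", "eas_specific", "eur_specific", "common")
  counts <- as.integer(stats::rmultinom(1L, m, config$pi))
  group <- rep("null", m)
  idx <- seq_len(m)
  if (config$shared_low_divergence && !is.null(freqs) && counts[4L] > 0L) {
    mafcv <- two_value_cv(pmin(freqs$p1, 1 - freqs$p1),
                          pmin(freqs$p2, 1 - freqs$p2))
    ok <- mafcv <= stats::quantile(mafcv, 0.5, na.rm = TRUE)
    if (!is.null(block_rho1) && !is.null(block_rho2) &&
        any(block_rho1 > 0 | block_rho2 > 0)) {
      # compare the blocks' expected LD scores, not their latent rho:
      # the rho -> LD-score map is convex, so equal-rho-gap blocks can
      # still have very different scores at high LD
      ell_proxy <- function(rho) {
        1 + 2 * sum((0.64 * rho^seq_len(config$block_size - 1L))^2)
      }
      e1 <- vapply(block_rho1, ell_proxy, numeric(1L))
      e2 <- vapply(block_rho2, ell_proxy, numeric(1L))
      ellcv <- two_value_cv(e1, e2)
      blk <- (idx - 1L) %/% config$block_size + 1L
      ok <- ok & (ellcv <= stats::quantile(ellcv, 0.3))[blk]
    }
    eligible <- idx[ok]
    if (length(eligible) < counts[4L]) eligible <- idx  # degenerate fallback
    shared <- sample(eligible, counts[4L])
  } else {
    shared <- sample(idx, counts[4L])
  }
  group[shared] <- "common"
  rest <- sample(setdiff(idx, shared))
  group[rest[seq_len(counts[2L])]] <- "eas_specific"
  group[rest[counts[2L] + seq_len(counts[3L])]] <- "eur_specific"
  group
}

#' Simulate marginal GWAS summary statistics (analytic route)
#'
#' Draws per-SNP Z statistics around their expectations
#' `sqrt(n) * (R %*% beta_std)` with covariance equal to the block LD
#' matrix `R`; without LD (`ld_rho = 0` or no panel) the statistics are
#' independent normals. Per-allele effects, standard errors
#' (`se = 1 / sqrt(2 p (1-p) n)`, with `beta = z * se` so `beta/se = z`
#' exactly), P values, sample size and MAF are filled in.
#'
#' @param truth a [assign_effects()] result.
#' @param freqs the matching [simulate_frequencies()] result.
#' @param n GWAS sample size.
#' @param population 1 or 2 (selects effects, frequencies, seed stream).
#' @param panel optional [genotype_panel] supplying block LD.
#' @return a [sumstat_table].
#' @export
simulate_sumstats <- function(truth, freqs, n, population = 1L,
                              panel = NULL) {
  config <- attr(truth, "config")
  if (n < 50) warning("simulate_sumstats: n < 50 gives unstable standard errors")
  bstd <- if (population == 1L) truth$beta1_std else truth$beta2_std
  p <- if (population == 1L) freqs$p1 else freqs$p2
  seed <- stage_seed(config, if (population == 1L) "gwas1" else "gwas2")
  m <- config$m
  with_preserved_seed(seed, {
    if (is.null(panel) || config$ld_rho == 0) {
      z <- stats::rnorm(m, sqrt(n) * bstd, 1)
    } else {
      x <- standardize_dosage(panel$dosage)
      nref <- nrow(x)
      z <- numeric(m)
      bs <- config$block_size
      for (s in seq(1L, m, by = bs)) {
        e <- min(s + bs - 1L, m)
        idx <- s:e
        r <- crossprod(x[, idx, drop = FALSE]) / (nref - 1L)
        r <- r + diag(1e-6, length(idx))
        mu <- sqrt(n) * as.numeric(r %*% bstd[idx])
        z[idx] <- mu + as.numeric(t(chol(r)) %*% stats::rnorm(length(idx)))
      }
    }
    maf <- pmin(p, 1 - p)
    se <- 1 / sqrt(2 * p * (1 - p) * n)
    meta <- sim_snp_meta(m)
    sumstat_table(data.frame(
      snp_id = meta$id, chrom = meta$chrom, pos = meta$pos,
      effect_allele = meta$alt, other_allele = meta$ref,
      beta = z * se, se = se, z = z, n = n, maf = maf,
      stringsAsFactors = FALSE))
  })
}

#' Simulate summary statistics from explicit phenotypes
#'
#' Validation route for [simulate_sumstats()]: generates `n` individual
#' genotypes with the same copula, builds phenotypes
#' `y = X_std %*% beta_std + e` with environmental variance `1 - h2`,
#' and runs the per-SNP marginal regression. Slow; intended for small
#' cross-validation runs.
#'
#' @inheritParams simulate_sumstats
#' @return a [sumstat_table].
#' @export
simulate_sumstats_explicit <- function(truth, freqs, n, population = 1L) {
  config <- attr(truth, "config")
  bstd <- if (population == 1L) truth$beta1_std else truth$beta2_std
  p <- if (population == 1L) freqs$p1 else freqs$p2
  h2 <- if (population == 1L) config$h2_1 else config$h2_2
  seed <- stage_seed(config, if (population == 1L) "pheno1" else "pheno2")
  with_preserved_seed(seed, {
    g <- simulate_genotypes(p, n, config, seed = seed + 1L)$dosage
    xs <- standardize_dosage(g)
    y <- as.numeric(xs %*% bstd) + stats::rnorm(n, 0, sqrt(max(0, 1 - h2)))
    # per-SNP simple regression of y on raw dosage
    gc <- sweep(g, 2L, colMeans(g), "-")
    yc <- y - mean(y)
    sxx <- colSums(gc^2)
    sxy <- as.numeric(crossprod(gc, yc))
    slope <- sxy / sxx
    syy <- sum(yc^2)
    s2 <- pmax(syy - slope * sxy, 0) / (n - 2L)
    se <- sqrt(s2 / sxx)
    z <- slope / se
    meta <- sim_snp_meta(config$m)
    sumstat_table(data.frame(
      snp_id = meta$id, chrom = meta$chrom, pos = meta$pos,
      effect_allele = meta$alt, other_allele = meta$ref,
      beta = slope, se = se, z = z, n = n, maf = pmin(p, 1 - p),
      stringsAsFactors = FALSE))
  })
}

#' Simulate a complete two-population study
#'
#' Runs frequencies, effect assignment, optional reference panels, and
#' both populations' summary statistics in one call.
#'
#' @param config a [sim_config()].
#' @param panels generate reference genotype panels (default `TRUE`;
#'   switch off for summary-statistic-only studies).
#' @return list with `config`, `freqs`, `truth`, `panel_eas`,
#'   `panel_eur` (or `NULL`), `ss_eas`, `ss_eur`.
#' @export
simulate_study <- function(config, panels = TRUE) {
  freqs <- simulate_frequencies(config)
  rho1 <- block_ld_rho(config, 1L)
  rho2 <- block_ld_rho(config, 2L)
  truth <- assign_effects(config, freqs, rho1, rho2)
  panel1 <- panel2 <- NULL
  if (panels) {
    panel1 <- simulate_genotypes(freqs$p1, config$n_ref[1L], config,
                                 seed = stage_seed(config, "geno1"),
                                 block_rho = rho1)
    panel2 <- simulate_genotypes(freqs$p2, config$n_ref[2L], config,
                                 seed = stage_seed(config, "geno2"),
                                 block_rho = rho2)
  }
  list(config = config, freqs = freqs, truth = truth,
       block_rho = list(rho1, rho2),
       panel_eas = panel1, panel_eur = panel2,
       ss_eas = simulate_sumstats(truth, freqs, config$n1, 1L, panel1),
       ss_eur = simulate_sumstats(truth, freqs, config$n2, 2L, panel2))
}

#' Write a self-contained synthetic fixture directory
#'
#' Writes both populations' summary statistics (TSV), both reference
#' panels (uncompressed VCF), the ground truth (TSV) and the
#' configuration (YAML). Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param outdir writable directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
make_fixture <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config, panels = TRUE)
  paths <- c(
    sumstats_eas = file.path(outdir, "sumstats_eas.tsv"),
    sumstats_eur = file.path(outdir, "sumstats_eur.tsv"),
    panel_eas = file.path(outdir, "panel_eas.vcf"),
    panel_eur = file.path(outdir, "panel_eur.vcf"),
    truth = file.path(outdir, "truth.tsv"),
    config = file.path(outdir, "config.yaml")
  )
  write_sumstats(study$ss_eas, paths[["sumstats_eas"]])
  write_sumstats(study$ss_eur, paths[["sumstats_eur"]])
  write_panel_vcf(study$panel_eas, paths[["panel_eas"]])
  write_panel_vcf(study$panel_eur, paths[["panel_eur"]])
  tr <- as.data.frame(study$truth)
  tr$rho_g_true <- attr(study$truth, "rho_g_true")
  utils::write.table(format(tr, digits = 17, trim = TRUE),
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(unclass(config), paths[["config"]])
  invisible(paths)
}
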