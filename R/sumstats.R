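#' Construct a summary-statistic table
#'
#' A `sumstat_table` holds one trait x one population of marginal GWAS
#' results: per-SNP effect size (log odds ratio for binary traits),
#' standard error, signed Z statistic, two-sided P value, sample size and
#' minor allele frequency. Missing `z` is filled from `beta/se`; missing
#' `p` from the two-sided normal tail of `z`.
#'
#' @param df data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, and at least (`beta`, `se`) or `z`;
#'   optional `p`, `n`, `maf`.
#' @param recompute_p if `TRUE`, always recompute `p` from `z` (used after
#'   transformations that change `z`).
#' @param allow_duplicates keep duplicated `snp_id` rows (used by the
#'   reader so that QC can remove them; default `FALSE`).
#' @return data.frame of class `sumstat_table`.
#' @export
sumstat_table <- function(df, recompute_p = FALSE, allow_duplicates = FALSE) {
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("sumstat_table: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!allow_duplicates && anyDuplicated(df[["snp_id"]])) {
    stop("sumstat_table: snp_id must be unique (",
         sum(duplicated(df[["snp_id"]])), " duplicates)")
  }
  # note: [[ ]] accessors throughout; $ would partially match (p -> pos)
  for (col in c("beta", "se", "z", "p", "n", "maf")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  fill <- is.na(df[["z"]]) & !is.na(df[["beta"]]) & !is.na(df[["se"]])
  df[["z"]][fill] <- df[["beta"]][fill] / df[["se"]][fill]
  fill_p <- recompute_p | is.na(df[["p"]])
  df[["p"]][fill_p] <- two_sided_p(df[["z"]][fill_p])
  df[["effect_allele"]] <- toupper(as.character(df[["effect_allele"]]))
  df[["other_allele"]]  <- toupper(as.character(df[["other_allele"]]))
  rownames(df) <- NULL
  class(df) <- c("sumstat_table", "data.frame")
  df
}

#' Two-sided normal tail probability of a Z statistic
#'
#' @param z numeric vector.
#' @return two-sided P values in (0, 1].
#' @export
two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Read GWAS summary statistics from delimited text
#'
#' Reads a whitespace- or tab-delimited file with a header, mapping its
#' column names onto the canonical fields through `dialect`. Odds ratios
#' are converted to the log scale; `z` and `p` are filled when absent.
#' Rows missing a mandatory value are dropped with a message.
#'
#' @param path file path.
#' @param dialect named list (or path to a YAML file holding one) mapping
#'   canonical fields (`snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta` or `or`, `se`, `z`, `p`, `n`, `maf`) to column
#'   names in the file. Supplying `or` declares the effect column to be an
#'   odds ratio.
#' @param sep field separator, default `""` (any whitespace).
#' @return a [sumstat_table].
#' @export
read_sumstats <- function(path, dialect, sep = "") {
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect)) {
    dialect <- yaml::read_yaml(dialect)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  has_or <- !is.null(dialect$or)
  effect_field <- if (has_or) "or" else "beta"
  for (fld in c(mandatory, effect_field, "se")) {
    cn <- dialect[[fld]]
    if (is.null(cn)) stop("read_sumstats: dialect lacks mapping for '", fld, "'")
    if (!cn %in% names(raw)) {
      stop("read_sumstats: file lacks column '", cn, "' (mapped to '", fld, "')")
    }
  }
  out <- data.frame(
    snp_id = as.character(raw[[dialect$snp_id]]),
    chrom = as.character(raw[[dialect$chrom]]),
    pos = parse_numeric(raw[[dialect$pos]], path, dialect$pos),
    effect_allele = as.character(raw[[dialect$effect_allele]]),
    other_allele = as.character(raw[[dialect$other_allele]]),
    se = parse_numeric(raw[[dialect$se]], path, dialect$se),
    stringsAsFactors = FALSE
  )
  eff <- parse_numeric(raw[[dialect[[effect_field]]]], path, dialect[[effect_field]])
  out$beta <- if (has_or) log(eff) else eff
  for (fld in c("z", "p", "n", "maf")) {
    cn <- dialect[[fld]]
    if (!is.null(cn) && cn %in% names(raw)) {
      out[[fld]] <- parse_numeric(raw[[cn]], path, cn)
    }
  }
  keep <- !is.na(out$snp_id) & !is.na(out$beta) & !is.na(out$se) & out$se > 0
  if (any(!keep)) {
    message("read_sumstats: dropped ", sum(!keep),
            " row(s) with missing mandatory values")
    out <- out[keep, , drop = FALSE]
  }
  sumstat_table(out, allow_duplicates = TRUE)
}

parse_numeric <- function(x, path, col) {
  if (is.numeric(x)) return(as.numeric(x))
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(v))
  if (length(bad) > 0L) {
    stop("read_sumstats: unparseable numeric in '", col, "' of ", path,
         " at data line ", bad[1L], " (value '", x[bad[1L]], "')")
  }
  v
}

#' Write a summary-statistic table as tab-delimited text
#'
#' @param ss a [sumstat_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  df <- as.data.frame(ss)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  a1 %in% names(COMPLEMENT) & a2 %in% names(COMPLEMENT) &
    unname(COMPLEMENT[a1]) == a2
}

#' Quality-control filter for summary statistics against a reference panel
#'
#' Applies, in order: (i) drop SNPs without an rs identifier; (ii) drop
#' non-biallelic / non-ACGT records; (iii) drop SNPs whose alleles do not
#' match the reference panel (allowing strand complement and allele swap);
#' (iv) drop duplicated identifiers; (v) drop palindromic (A/T, C/G)
#' SNPs, which are strand-ambiguous; (vi) keep SNPs present in the panel
#' with MAF above `maf_min`, imputing MAF from the panel where the study
#' did not report one.
#'
#' @param ss a [sumstat_table].
#' @param panel a [genotype_panel] providing reference alleles and
#'   frequencies.
#' @param maf_min minor-allele-frequency threshold (default 0.01,
#'   exclusive).
#' @return filtered [sumstat_table]; attribute `qc_log` records SNPs
#'   removed at each step.
#' @export
qc_filter <- function(ss, panel, maf_min = 0.01) {
  log <- integer(0)
  step <- function(tab, keep, name) {
    log[[name]] <<- sum(!keep)
    out <- tab[keep, , drop = FALSE]
    if (nrow(out) == 0L) {
      stop("qc_filter: no SNPs remain; last rows removed at step '", name, "'")
    }
    out
  }
  tab <- as.data.frame(ss)
  tab <- step(tab, grepl("^rs[0-9]+$", tab$snp_id), "rs_label")
  ok_base <- tab$effect_allele %in% names(COMPLEMENT) &
    tab$other_allele %in% names(COMPLEMENT) &
    tab$effect_allele != tab$other_allele
  tab <- step(tab, ok_base, "biallelic")
  meta <- panel$snp_meta
  idx <- match(tab$snp_id, meta$id)
  in_panel <- !is.na(idx)
  pa1 <- meta$ref[idx]; pa2 <- meta$alt[idx]
  match_direct <- in_panel &
    ((tab$effect_allele == pa1 & tab$other_allele == pa2) |
     (tab$effect_allele == pa2 & tab$other_allele == pa1))
  ca1 <- unname(COMPLEMENT[tab$effect_allele])
  ca2 <- unname(COMPLEMENT[tab$other_allele])
  match_comp <- in_panel &
    ((ca1 == pa1 & ca2 == pa2) | (ca1 == pa2 & ca2 == pa1))
  tab <- step(tab, !in_panel | match_direct | match_comp, "allele_match")
  tab <- step(tab, !duplicated(tab$snp_id), "duplicates")
  tab <- step(tab, !is_palindromic(tab$effect_allele, tab$other_allele),
              "palindromic")
  idx <- match(tab$snp_id, meta$id)
  panel_maf <- compute_maf(panel)[idx]
  use_maf <- ifelse(is.na(tab$maf), panel_maf, tab$maf)
  tab$maf <- use_maf
  tab <- step(tab, !is.na(idx) & !is.na(use_maf) & use_maf > maf_min,
              "panel_maf")
  out <- sumstat_table(tab)
  attr(out, "qc_log") <- log
  out
}

#' Harmonize two QC'd summary-statistic tables onto shared SNPs
#'
#' Restricts both tables to their shared SNP identifiers and aligns the
#' effect allele of the second population onto the first: where the
#' effect/other alleles are swapped (directly or as strand complements),
#' the second table's `beta` and `z` are negated and its allele frequency
#' complemented, and the SNP is flagged `flipped`. Irreconcilable allele
#' pairs are dropped and counted.
#'
#' @param eas,eur [sumstat_table]s for the two populations (names follow
#'   the East-Asian / European use case; any two populations work).
#' @return list of class `harmonized_pair` with elements `snps`, `eas`,
#'   `eur`, `flipped`, and `n_dropped_irreconcilable`.
#' @export
harmonize_pair <- function(eas, eur) {
  shared <- intersect(eas$snp_id, eur$snp_id)
  a <- as.data.frame(eas)[match(shared, eas$snp_id), , drop = FALSE]
  b <- as.data.frame(eur)[match(shared, eur$snp_id), , drop = FALSE]
  same <- a$effect_allele == b$effect_allele & a$other_allele == b$other_allele
  comp <- unname(COMPLEMENT[b$effect_allele]) == a$effect_allele &
    unname(COMPLEMENT[b$other_allele]) == a$other_allele
  swapped <- a$effect_allele == b$other_allele & a$other_allele == b$effect_allele
  swapped_comp <- unname(COMPLEMENT[b$other_allele]) == a$effect_allele &
    unname(COMPLEMENT[b$effect_allele]) == a$other_allele
  ok_same <- same | (comp & !same)
  ok_swap <- (swapped | swapped_comp) & !ok_same
  keep <- ok_same | ok_swap
  n_drop <- sum(!keep)
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  flip <- ok_swap[keep]
  b$beta[flip] <- -b$beta[flip]
  b$z[flip] <- -b$z[flip]
  # maf is stored folded (minor allele), so relabelling alleles leaves it unchanged
  b$effect_allele <- a$effect_allele
  b$other_allele <- a$other_allele
  structure(
    list(snps = a$snp_id,
         eas = sumstat_table(a),
         eur = sumstat_table(b),
         flipped = flip,
         n_dropped_irreconcilable = n_drop),
    class = "harmonized_pair"
  )
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat("harmonized_pair:", length(x$snps), "shared SNPs,",
      sum(x$flipped), "sign-flipped,",
      x$n_dropped_irreconcilable, "dropped as irreconcilable\n")
  invisible(x)
}
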