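# transarch

Trans-ethnic comparison of complex-trait genetic architecture from GWAS
summary statistics.

## What problem this solves

GWAS of the same trait in two ancestral populations — the motivating case
is East Asian (EAS) vs European (EUR) cohorts — disagree for a mixture of
reasons: different allele frequencies and LD, population-specific causal
variants, heterogeneous effect sizes, and very different sample sizes.
`transarch` takes two per-trait summary-statistic files plus small
reference genotype panels and quantifies, stage by stage, how much of the
genetic architecture is shared and how much is population-specific:

- **QC + harmonization** of summary statistics onto an allele-aligned
  common SNP set (`read_sumstats`, `qc_filter`, `harmonize_pair`);
- **SNP heritability** per population by LD-score regression
  (`ld_scores`, `estimate_h2`), with a normal test for the
  cross-population difference, `u = (ĥ²₁ − ĥ²₂)/√(se₁² + se₂²)`
  (`h2_diff_test`);
- **trans-ethnic genetic-effect correlation** ρ_g — the correlation of
  per-SNP standardized effects between the populations — by a
  cross-population score regression without an intercept
  (`cross_ld_scores`, `trans_ethnic_rg`);
- **shared vs specific associated SNPs** by conditional and conjunction
  false discovery rates on decorrelated, LD-pruned statistics
  (`ld_prune`, `estimate_null_correlation`, `decorrelate`,
  `empirical_cfdr`, `classify_snps`), with the four-group uniform/Beta
  mixture model and likelihood-ratio test of overall overlap
  (`fit_four_group`);
- **effect-size concordance**: attenuation-corrected marginal correlation
  (`magic_corr`), no-intercept slope with a slope-=-1 test
  (`slope_no_intercept`), per-SNP Cochran's Q (`cochran_q`);
- **divergence statistics**: LD-score and MAF coefficients of variation
  and Weir–Cockerham / Hudson Fst across the four SNP groups
  (`two_value_cv`, `fst`, `divergence_table`, `group_kruskal`);
- **genetic risk scores** from overall / common / specific SNP sets with
  Z-based rescaling for continuous traits (`rescale_beta`, `compute_grs`,
  `grs_analysis`);
- a **two-population simulator** (Balding–Nichols frequencies, blockwise
  LD, four-group causal architecture with shared-effect correlation) that
  provides ground truth for every stage (`sim_config`, `simulate_study`,
  `make_fixture`), and a one-call orchestrator (`run_trait`).

## Worked example

A complete synthetic study, end to end:

```r
library(transarch)

cfg <- sim_config(m = 6000, ld_rho = 0.9, block_size = 10,
                  h2_1 = 0.3, h2_2 = 0.3, seed = 5)
st  <- simulate_study(cfg)
res <- run_trait(st$ss_eas, st$ss_eur, st$panel_eas, st$panel_eur,
                 trait_type = "continuous", n_blocks = 100, window_bp = 2e5)

res$classification
#> snp_classification (alpha = 0.05): k = 5270, f10 = 149, f01 = 466, f11 = 74

res$fourgroup
#> four-group fit: pi = (0.832, 0.053, 0.090, 0.025), alpha = (0.102, 0.034)
#>   shared proportion = 14.9%, LRT = 58.3, P = 2.24e-14

d <- res$divergence
mean(d$mafcv[d$group == "common"]); mean(d$mafcv[d$group == "null"])
#> [1] 0.196
#> [1] 0.344
```

Reading the output: of `k` = 5,270 pruned SNPs, 149 are called associated
only in the smaller-sample population (`f10`), 466 only in the larger
(`f01`) — the power asymmetry the simulator builds in — and 74 in both
(`f11`). The mixture model attributes ~15% of the non-null mass to the
shared group, and the likelihood-ratio test rejects independence of the
two populations' association indicators outright. Shared SNPs show
visibly smaller cross-population MAF divergence than null SNPs (0.20 vs
0.34), the conserved-architecture pattern the generator encodes.

The package also bundles published per-trait estimates for 37 complex
traits in EAS and EUR populations (`trait_estimates()`,
`snp_classification_counts()`), and summary reports over them:

```r
s <- summarize_table1(trait_estimates())
s$h2_correlation$r        # 0.738  — heritabilities agree across populations
s$n_h2_diff_significant   # 26     — of 37 traits differ after BH (70.3%)
s$rho_mean                # 0.787  — mean trans-ethnic genetic correlation
s$n_rho_lt1               # 19     — of 31 estimates significantly below 1

summarize_table2(snp_classification_counts())$pi11_mean_pct
#> 21.7  — mean % of trait-associated SNPs shared by both populations
```

## Documentation

The methods vignette (`vignettes/transethnic-architecture.Rmd`) describes
each model, the estimators and their assumptions, every tunable threshold
with its default, what the synthetic generator does and does not emulate,
and known limitations.
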