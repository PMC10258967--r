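Package: transarch
Title: Trans-Ethnic Comparison of Complex-Trait Genetic Architecture from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare the genetic architecture of complex traits
    between two ancestral populations (such as East Asian and European)
    using only GWAS summary statistics and small reference genotype
    panels. Implements summary-statistic quality control and allele
    harmonization, LD-score computation and LD-score-regression
    heritability with block-jackknife errors, a cross-population
    score-regression estimator of the trans-ethnic genetic-effect
    correlation, conditional and conjunction false discovery rates
    (cFDR/ccFDR) with Z-statistic decorrelation for four-way SNP
    classification, a four-group uniform/Beta mixture model with a
    likelihood-ratio test of genetic overlap, measurement-error-corrected
    effect-size correlation and Cochran's Q heterogeneity, per-SNP
    divergence statistics (LD and MAF coefficients of variation,
    Weir-Cockerham and Hudson Fst), and genetic risk scores with
    Z-based effect rescaling. A two-population Balding-Nichols simulator
    with blockwise LD and a four-group causal architecture provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
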