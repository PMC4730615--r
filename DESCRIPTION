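Package: tppassoc
Title: Two-Phase Nonparametric Trend Tests for Non-Normal Quantitative
    Trait Genetic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rank-based association tests between a biallelic SNP and a
    quantitative trait whose distribution is far from normal. Implements
    Mann-Whitney win-probability estimators with plug-in variance and
    covariance estimators, the nonparametric trend tests optimal under the
    recessive, additive and dominant genetic models, a model-selection
    statistic, and a two-phase procedure that first selects the genetic
    model and then tests association at an adjusted significance level
    solved from the joint bivariate-normal null distribution of the two
    phases' statistics. Includes Kruskal-Wallis and MAX3 comparators, a
    synthetic-cohort generator with truncated generalized-extreme-value
    errors, Monte Carlo experiment drivers for selection rates, adjusted
    levels, type I error and power, delimited/VCF cohort ingestion, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
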