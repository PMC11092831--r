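Package: mzvar
Title: Variance QTL Detection from Monozygotic Twin Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects variance quantitative trait loci (vQTLs) from monozygotic
    (MZ) twin pairs. Builds the absolute within-pair difference phenotype
    (covariate residualization, standardization, rank-based inverse normal
    transformation), tests it against genotype with ordinary least squares, and
    provides the population-based deviation regression model (DRM) as a
    comparator. Includes a generative simulator for twin and population cohorts
    with genotype-dependent variance inflation and LD-tagged locus pairs,
    analytic power calibration, power and false-discovery experiments,
    EasyQC-style summary-statistic quality control and harmonization,
    METAL-style inverse-variance-weighted fixed-effect meta-analysis, and
    two-sample Mendelian randomization of mean-effect instruments on variance
    outcomes with heterogeneity and stratum-difference tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
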