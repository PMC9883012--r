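Package: mrscreen
Title: Phenome-Wide Two-Sample Mendelian Randomisation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable implementation of a phenome-wide two-sample
    Mendelian randomisation (MR) screening framework: adaptive p-value-ladder
    instrument selection, LD clumping with proxy substitution, allele
    harmonisation, pleiotropy and radial-MR outlier filtering, a battery of
    causal estimators (IVW with fixed and multiplicative random effects,
    MR-Egger, weighted median, weighted mode) with a quality-control suite
    (Cochran's Q, Egger intercept, I-squared for the NOME assumption, mean
    F-statistic, leave-one-out), composite significance criteria under false
    discovery rate control, replication against a second outcome, multivariable
    MR with conditional F-statistics and Q-minimisation, and Bayesian model
    averaging (MR-BMA) over correlated risk factors. A synthetic GWAS
    summary-statistics generator with known ground truth makes every pipeline
    stage testable without external downloads.
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
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
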