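Package: mrmediation
Title: Two-Step and Multivariable Mendelian Randomization with Mediation
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection and allele harmonization,
    inverse-variance-weighted, MR-Egger, weighted-median,
    maximum-likelihood and robust-adjusted-profile-score estimators,
    heterogeneity and pleiotropy diagnostics including MR-PRESSO outlier
    detection, multivariable MR for direct effects, and two-step mediation
    analysis with the proportion-mediated decomposition. Includes a
    synthetic two-sample GWAS generator with known structural ground truth
    for validating every stage, and a config-driven pipeline that runs an
    exposure-mediator-outcome analysis graph end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    optparse,
    jsonlite
Config/testthat/edition: 3
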