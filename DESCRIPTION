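Package: semscan
Title: Latent-Factor Structural Equation Model GWAS with eQTL Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multi-trait genome-wide association scanning for symptom-complex
    phenotypes via a one-common-factor structural equation model: questionnaire
    delta-score preprocessing, partial-correlation network model specification by
    covariance selection, maximum-likelihood one-factor confirmatory fits with
    RMSEA diagnostics, per-variant latent-mediated association tests with genomic
    control, LD-based locus definition, and Bayesian GWAS-eQTL colocalization with
    Wakefield approximate Bayes factors. Includes genotype quality control
    (call rate, MAF, Hardy-Weinberg exact test, identity-by-descent, projection
    PCA for population stratification) and a synthetic-data generator emulating
    the statistical structure of a questionnaire-based eye-strain cohort for
    fully reproducible end-to-end runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    vcfR,
    igraph
Suggests: testthat (>= 3.0.0), numDeriv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
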