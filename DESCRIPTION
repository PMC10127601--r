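Package: strainstability
Title: Strain-Level Stability and Macroecology of Gut Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing the temporal dynamics of strains in densely
    sampled shotgun-metagenomic gut microbiome time series. Computes
    genome-wide nucleotide diversity (pi), between-timepoint diversity and
    fixation indices (FST, normalized FST'), classifies their stationarity
    with an augmented Dickey-Fuller test, phases conspecific strains by
    clustering SNV allele-frequency trajectories, fits the stochastic
    logistic model (SLM) of abundance fluctuations by moment matching and
    tests its goodness of fit by parametric bootstrap, and fits
    macroecological laws (Taylor's law, the gamma abundance-fluctuation
    distribution) across populations. Includes a synthetic-data generator
    with known ground truth so the full pipeline can be exercised and
    validated without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
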