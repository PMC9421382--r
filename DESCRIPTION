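Package: ewastrat
Title: Fetal Sex-Stratified Methylome Association Analysis for Infinium Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for stratified epigenome-wide association analysis of
    Infinium methylation array data: probe-level quality control, beta/M-value
    transformation, empirical-Bayes chip-effect adjustment, variable-CpG
    filtering, reference-based cell-type deconvolution with cell-composition
    principal-component covariates, mass-univariate per-CpG linear regression
    of methylation on depressive-symptom scores stratified by fetal sex,
    one-sided Kolmogorov-Smirnov testing of p-value-distribution uniformity,
    genomic-context enrichment with swappable reference sets, hypergeometric
    gene-set over-representation, and a synthetic cohort generator with
    planted sex-specific effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    yaml,
    sva
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
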