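Package: gxesleep
Title: Genome-Wide Gene-by-Sleep-Duration Interaction Analysis for Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide gene-by-sleep-duration
    interaction analysis of blood pressure traits: multi-population
    synthetic-cohort simulation with planted genetic and gene-environment
    effects, centralized phenotype harmonization (medication adjustment,
    winsorization, residual-percentile sleep exposures), per-variant
    interaction regression with heteroskedasticity-robust standard errors,
    one-degree-of-freedom and two-degree-of-freedom joint Wald tests,
    inverse-variance and joint meta-analysis with genomic-control
    correction across population groups, and locus discovery with two-step
    screening, false-discovery-rate control, clumping, and sex-heterogeneity
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
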