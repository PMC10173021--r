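Package: ohcapath
Title: Path-Analysis Mediation of Socioeconomic Disparities in Cardiac Arrest Survival
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify how socioeconomic position relates to survival
    after out-of-hospital cardiac arrest and to decompose that association into
    mediated pathways. Provides a synthetic registry generator with a
    configurable causal structure calibrated to published Korean cohort
    margins, stochastic regression imputation of missing Utstein variables,
    adjusted odds-ratio tables, Baron-Kenny mediator screening, a recursive
    observed-variable path model fitted by maximum likelihood on the covariance
    structure with robust (sandwich / mean-scaled) corrections and RMSEA, SRMR,
    GFI and CFI fit indices, and product-of-coefficients pathway effects with
    mediation proportions and delta-method or bootstrap confidence intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
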