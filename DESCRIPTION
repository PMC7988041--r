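Package: csfbc
Title: Boundary-Condition Comparison for Cerebrospinal Fluid Dynamics in
    Hydrocephalus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reduced-order pulsatile simulation of cerebrospinal fluid (CSF)
    flow through the ventricles, cerebral aqueduct and subarachnoid space
    with a poro-viscoelastic (Prony series) ventricular wall, under three
    inlet/outlet boundary-condition schemes (sinusoidal pressure, pulsatile
    flow with constant outlet pressure, and pulsatile flow at both inlet and
    outlets).  Computes the hydrodynamic summary metrics used to compare the
    schemes (aqueductal stroke volume, Reynolds number, peak pressures and
    phases), ships verbatim cohort tables for eight healthy subjects and
    eleven hydrocephalus patients, and provides the complete statistical
    layer (descriptives, coefficient of variation, confidence intervals,
    Shapiro-Wilk, ANOVA with Tukey HSD, pooled t tests, Pearson correlation)
    together with a claims report that recomputes every derived cohort
    quantity from the bundled tables.  A seeded synthetic-cohort generator
    makes the full pipeline testable without any external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
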