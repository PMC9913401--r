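Package: depnetsurv
Title: Deprivation Gaps in Cancer Net Survival Under Alternative Life Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sensitivity analyses of social gradients in cancer net
    survival with respect to the deprivation stratification of the background
    life tables. Provides deprivation-stratified life-table simulation by
    rate-ratio transfer from an external mortality-gradient source,
    non-parametric net survival estimation (Pohar-Perme) with age
    standardization and quintile deprivation gaps, flexible excess-mortality
    hazard regression with multidimensional penalized splines and
    corrected-AIC model selection among four deprivation-effect forms,
    registry-like cohort simulation with known ground truth, and an
    orchestrated three-analysis comparison report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
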