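Package: stoichdiet
Title: Dietary Stoichiometry, Cancer Rates and Life Expectancy at the Country Level
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for country-level analyses linking the
    elemental composition of national diets (nitrogen, phosphorus and their
    N:P mass ratio, protein, kilocalories and total intake by food source)
    to cancer prevalence, cancer mortality and life expectancy. Builds
    per-capita nutrient intake covariates from food-balance and
    nutrient-concentration tables, computes age-standardized outcome rates
    against a standard population, reduces the collinear covariate set by
    correlation clustering (Kelley criterion) with per-cluster principal
    components, fits Bayesian spike-and-slab (stochastic search variable
    selection) regressions by Gibbs sampling, and maps factor coefficients
    back to the original covariates. Includes a synthetic country-panel
    generator with known ground truth so the full pipeline can be validated
    by parameter-recovery simulation, plus reduced major-axis bivariate
    fits and variance-inflation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
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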