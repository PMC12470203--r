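Package: teatrace
Title: Cadmium and Selenium Transfer in the Soil-Tea-Infusion Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for tracing cadmium (Cd) and selenium (Se) through the
    soil - tea tree - tea infusion continuum of Se-enriched tea gardens.
    Implements the standard ratio indices of soil-plant transfer studies
    (single-factor pollution index, activation rate, organ enrichment and
    transport coefficients, infusion leaching rate), the USEPA-style
    carcinogenic risk chain for Cd intake from brewed tea, and the
    accompanying statistical layer: Pearson correlation matrices with
    significance stars, one-way ANOVA with protected LSD post-hoc tests and
    compact letter displays (including a summary-statistics variant for
    published mean +/- sd tables), ordinary linear regression with
    confidence bands, and discontinuous two-phase (threshold) regression
    with breakpoint search. A synthetic-study generator reproduces the
    multiplicative organ-chain structure of such surveys so that every
    pipeline stage is testable by parameter recovery. A bundled reference
    survey of twelve Se-enriched tea gardens is included as plain-text
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
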