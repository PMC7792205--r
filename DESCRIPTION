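Package: sroikit
Title: Social Return on Investment Valuation for Health Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven Social Return on Investment (SROI) valuation
    engine for health programs. Values preventable-condition outcomes from
    prevalence and breastfeeding-attributable risk reductions priced with
    financial proxies, applies deadweight/displacement/attribution impact
    adjustments and drop-off decay, discounts benefit streams to net present
    value, and reports SROI ratios, net yield and payback period. Includes a
    built-in Baby-Friendly Hospital Initiative (BFHI) maternity-unit case
    study, one-way deterministic sensitivity analysis with tornado ranking, a
    seeded Monte Carlo extension, and a seeded generator of synthetic
    scenarios for property-based testing.
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
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
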