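Package: firefreq
Title: Fire Frequency Analysis with the Discrete Lognormal Interval Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for landscape fire-frequency analysis from multi-year
    burned-area records. Extracts complete and single-censored fire-interval
    samples from annual burn masks on a regular point grid, fits a discrete
    lognormal interval model by maximum likelihood with right- and
    left-censored terms, and derives survival and hazard-of-burning curves,
    median, modal and turning-point fuel ages, fire rotation periods and
    annual percent area burned per land-cover class. Includes a censored-data
    goodness-of-fit test standardized to a normal scale via a parametric
    bootstrap, a renewal-process landscape simulator for validation studies,
    and a reporting pipeline that writes per-class summary tables and
    distribution curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
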