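Package: wallmech
Title: Cell Wall Creep Biomechanics from Constant-Load Extensometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vitro plant cell wall biomechanics
    measured by constant-load creep extensometry. Converts raw creep traces
    into relative creep rates, derives cell wall cross-section areas and
    tensile stresses from segment dry masses, estimates creep rate per unit
    stress by bootstrap resampling with false-discovery-rate-controlled
    group comparisons, and fits errors-in-both-variables (Deming, maximum
    likelihood functional relationship) regressions of creep rate on wall
    stress to estimate in vitro cell wall extensibility (slope) and yield
    threshold (x-intercept) with leave-one-out jackknife standard errors.
    Includes a synthetic-data generator that emulates the two-group,
    four-load design of typical hypocotyl creep experiments so the whole
    pipeline is testable without instrument data.
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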