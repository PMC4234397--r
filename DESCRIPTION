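Package: averted
Title: Deterministic Lives-Saved Cascade Modelling of Child Diarrhea Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, linear lives-saved model that converts changes in
    intervention coverage into diarrhea deaths averted among children aged 1 to
    59 months. Interventions act through direct efficacy cascades applied to
    residual deaths (preventing double counting), etiology- and
    deficiency-specific affected fractions, breastfeeding pattern promotion
    with proportional redistribution of sub-optimal feeding categories, and
    indirect risk-factor pathways in which reduced diarrhea incidence shifts
    the stunting distribution and thereby the mortality risk. Includes
    parameter-pack and scenario readers with schema validation, deterministic
    reporting, a seeded fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
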