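Package: fgfcds
Title: Fresh Gas Flow Clinical Decision Support, Anesthetic Consumption Metrics, and Case Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A per-minute rule engine that raises low-flow advisories when the
    fresh gas flow (FGF) delivered with a volatile anesthetic exceeds a
    configurable threshold, together with the reporting pipeline that expresses
    anesthetic consumption as mL of liquid agent per MAC-hour at case and
    professional granularity, and a synthetic operating-room case simulator
    with a probabilistic practitioner response to alerts so that every
    component can be exercised end to end without clinical data. Includes
    agent physical constants with vapor/liquid conversion, age-adjusted MAC,
    site configuration presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
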