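Package: coiburden
Title: Cost-of-Illness Burden Estimation for Dementia Across Countries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates country-level dementia prevalence and economic burden.
    Applies an age-band by sex prevalence schedule to population pyramids to
    obtain case counts, scales direct care costs from GDP per capita (PPP) by
    World Bank income class, prices informal caregiver time under bracketing
    best/worst scenarios, and aggregates direct, indirect and total costs to
    country and region level, including cost as a percentage of GDP. Ships a
    synthetic-data generator with an independent loop-based oracle so the full
    pipeline is testable without external data extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
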