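Package: debtprior
Title: Threat-Adjusted Cost-Effectiveness Prioritization for Marine
    Debt-for-Nature Conversions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-support tools for prioritizing sovereign
    debt-conversion (debt-for-nature swap) opportunities for marine
    conservation. Implements a three-step framework: screening of
    candidate countries by enabling conditions (e.g. debt-to-GDP
    thresholds), a threat-adjusted cost-effectiveness score that
    separates human impacts a marine protected area can abate from
    those it cannot, and scenario-matrix sensitivity analysis with
    Jaccard set-overlap comparison of top-priority sets. Includes a
    seeded synthetic country-data generator so the full pipeline runs
    without external data, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
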