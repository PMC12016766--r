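Package: climvuln
Title: Trait-Based Climate-Change Vulnerability Assessment for Terrestrial Mammals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a trait-based vulnerability assessment (TVA) pipeline for
    terrestrial mammal faunas: standardized Euclidean distance (SED) climate-novelty
    mapping from gridded monthly climate series, per-species exposure scoring from
    presence-only occurrence grids, three-point trait scoring of sensitivity and
    adaptive-capacity axes with a tercile break-shift robustness test, combination of
    the three vulnerability dimensions into eight discrete categories, and an audit of
    how those categories are represented in general wildlife-disease surveillance
    records. Includes a synthetic-data generator emulating the statistical structure
    of the real inputs and a packaged species-to-category reference table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
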