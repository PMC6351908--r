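Package: lapmd
Title: Land-Use-Based Emission Inventories and Long-Term Multi-Source
    Gaussian Dispersion for Planning Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds annual SO2 and PM10 emission inventories organised by
    land-use source category (mass-balance and emission-factor methods),
    rasterizes them to per-cell source intensities, disperses them with a
    long-term eight-sector-averaged Gaussian multi-source model driven by a
    wind rose and Pasquill-Gifford dispersion coefficients, classifies the
    resulting annual concentration fields into pollution levels, and
    overlays them with land-use-planning maps to tabulate affected areas.
    Includes a seeded synthetic toy-city generator so the full pipeline is
    testable without external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, utils, tools
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
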