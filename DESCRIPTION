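Package: olivesim
Title: Process-Based Simulation of Water Use, Growth and Yield of Olive Orchards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily process-based simulator of olive orchard development, growth,
    water use and yield. Couples a two-zone multilayer soil water balance
    (canopy rainfall interception, curve-number runoff, tipping-bucket drainage
    and redistribution, two-stage soil evaporation with microadvection) to a
    soil-plant-atmosphere hydraulic network solved jointly with sunlit/shaded
    leaf gas exchange, and to a carbon economy with phenology, fruit-priority
    allocation, alternate bearing, senescence, frost and heat damage, soil
    carbon turnover and management operations (tillage, irrigation, harvest,
    pruning). Includes a seeded synthetic Mediterranean weather generator and
    model-evaluation statistics (MAE, RMSE, CRM, modelling efficiency, OLS
    diagnostics, biennial aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
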