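Package: dietledger
Title: Plate-Event Dietary Records, Recipe Decomposition and Nutrient Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for dietary assessment from plate-level consumption
    records collected by RFID-instrumented cafeteria plates. Ingests
    plate-event streams, applies a four-stage record selection procedure,
    decomposes consumed dishes into raw ingredients via a recipe database,
    computes per-100 g and per-serving nutrient content from a food
    composition table, aggregates intake per consumer and per day, produces
    population-level dish-type, preparation-method and ingredient-category
    distributions and per-consumer food-frequency tables, and validates
    calculated nutrient values against chemical reference measurements
    using mean absolute percentage deviation (MAPD). A seeded simulator
    generates synthetic menus, composition tables and multi-week event
    streams so the full pipeline is testable without proprietary data.
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
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
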