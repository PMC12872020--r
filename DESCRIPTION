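Package: CanopyPlan
Title: Urban Forest Assessment and Diversity-Driven Planting Recommendation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Assessment of urban tree inventories and decision support for
    diversification planting. Computes species and functional-group richness
    and exp-Shannon effective numbers (Hill number of order 1), diameter-class
    structure, compliance with the 10-20-30 / 5-10-15 composition rules,
    allometric biomass by compartment with root estimation and an open-grown
    correction, carbon storage and its monetary value at the social cost of
    carbon. Recommends candidate species to plant by simulating the addition
    of one tree per candidate, scoring the relative improvement of five
    criteria with user weights, and simulates full planting plans with
    before/after accounting. Includes a seeded synthetic-inventory generator
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
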