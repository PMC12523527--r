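Package: karstprior
Title: Conservation Prioritization of Karst Cave Invertebrate Biodiversity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based spatial prioritization of caves for invertebrate
    conservation. Computes four per-cave criteria (non-troglobite richness,
    troglobite richness, stenoendemic troglobite count, and vulnerability from
    anthropogenic impact types within a buffer), maps them to weighted
    categories, aggregates cave scores onto a rectangular analysis grid by
    per-attribute maxima, sums the layers into a composite conservation value
    (map algebra), and classifies occupied cells into priority tiers with an
    exact Fisher-Jenks natural-breaks algorithm. Includes first-order
    jackknife richness estimation for survey completeness and a seeded
    synthetic-karst data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
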