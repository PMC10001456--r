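Package: mast
Title: Menu Assessment Scoring Tool for Food Service Menus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-based assessment of the nutritional quality of food
    service menus using a risk-based penalty-point score. Provides a
    configurable food-category/food-group taxonomy aligned to the
    Australian Guide to Healthy Eating, a deterministic cue-lexicon
    classifier that assigns menu items to nutrient-poor or nutritious
    category slots (items are assumed nutrient-poor unless the menu text
    demonstrates otherwise), the penalty-point scoring system with its
    engaged-category denominator, batch summary reporting with
    per-outlet improvement signals, and a seeded synthetic menu
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    tibble,
    dplyr,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
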