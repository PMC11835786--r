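Package: mealrec
Title: Hybrid Healthy-Meal Recommender with Nutrient-Profile Scoring and
    Explanations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid recommender engine for workplace catering menus.
    Daily nutrient intake is estimated from food frequency questionnaire
    (FFQ) responses via a food-composition table and classified Low,
    Normal or High per nutrient against editable reference ranges. The
    resulting nutrient-status profile drives a knowledge-based scorer
    through a dietitian-style weight table, combined at fixed 65/25/10
    weights with an ingredient-based content score and a nearest-neighbour
    collaborative score, after a contextual prefilter for location,
    allergens, lifestyle constraints and meal repetition. Every
    recommendation carries three recomputable explanation payloads
    (nutritional alignment, past choices, popularity). Includes
    deterministic synthetic-data generators for menus, users, FFQ
    responses and multi-week order histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
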