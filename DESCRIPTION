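Package: npmprofiler
Title: Sales-Weighted Nutrient Profile Classification of Food and
    Beverage Company Portfolios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify what proportion of a food and beverage
    company's value sales derives from products classified as unhealthy
    under the WHO Regional Office for Europe nutrient profile model
    (First Edition, 2015). Implements a data-driven threshold rules
    engine over per-100 g/ml nutrient panels, lexicon-based detection of
    added sugars and non-sugar sweeteners in free-text ingredient lists,
    normalized brand-to-product record linkage with equal-split
    allocation of brand sales across product variants, and
    company/category aggregation with coverage accounting and
    engagement-threshold verdicts. Includes a synthetic market generator
    with planted ground truth so the full pipeline is testable without
    licensed sales or composition data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
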