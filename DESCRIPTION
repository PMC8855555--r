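Package: aquarisk
Title: Dietary Heavy-Metal Risk Assessment and Hazard Decision Trees for
    Aquatic Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for non-carcinogenic dietary risk assessment of heavy
    metals in aquatic products. Simulates consumption-survey populations and
    tissue-concentration samples with seeded, moment-matched distributions;
    computes per-subject estimated daily intake (EDI), hazard quotient (HQ)
    and the maximum safe intake (ADI) for 12 metals across 7 aquatic-product
    categories; induces per-metal binary hazard decision trees over category,
    body weight and food intake using the gain-ratio criterion with a
    two-stage construct/evaluate protocol; and extracts leaf-level risk rules
    mapped to health endpoints, rendered as text, CSV, JSON and DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
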