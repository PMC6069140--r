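Package: pharmwsv
Title: Rapid Derivation of Water Screening Values for Active
    Pharmaceutical Ingredients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a rapid risk-assessment framework for deriving
    screening reference doses (sRfD) and drinking-water screening values
    (WSV) for active pharmaceutical ingredients from structured,
    label-derived evidence profiles.  The lowest therapeutic dose serves
    as the point of departure; a decision tree assigns six uncertainty
    and adjustment factors (intraspecies variability, LOAEL-to-NOAEL
    extrapolation, database deficiencies, duration of use, threshold
    carcinogenicity, and endocrine activity) that are combined with
    half-log arithmetic.  Ships a published 119-compound screening value
    table together with one-directional validation tooling, aggregate
    statistics, protection-ratio comparison against in-depth
    health-based guidance values, and screening of monitoring detections
    against the derived values.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
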