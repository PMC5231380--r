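Package: momentumcf
Title: Counterfactual Trend Analysis of Conflict Impacts on Health Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the direct and opportunity costs of armed conflict on
    public health by comparing achieved infant and maternal mortality against
    counterfactual trajectories that extend pre-war momentum. Implements
    two-point average annual rate-of-change estimation, compound (and linear,
    exponential, logarithmic) counterfactual projection, worse/better/same
    classification of rates and endpoint levels, a 0-4 additive conflict
    impact index, headline tallies, a projection-shape sensitivity analysis,
    and a synthetic indicator-panel generator with known ground truth.
    Ships the published Sri Lanka 1982-2002 district and national tables as
    plain-text fixtures, and exports classification tables, tally summaries,
    reconciliation reports and choropleth-ready GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
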