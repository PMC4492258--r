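Package: monitorharm
Title: Harmonization and Simplified Spatiotemporal Modeling of Multi-Network
    PM2.5 Component Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining fine-particulate (PM2.5) component
    measurements collected under heterogeneous monitoring designs: a
    cohort-focused campaign with two-week integrated samples at fixed and
    rotating home-outdoor sites, and regulatory speciation networks with
    24-hour samples every third or sixth day. Provides alignment of all
    records to a common two-week period grid centered on alternate
    Wednesdays, log transformation policies, co-located monitor
    comparability statistics (correlation, best-fit lines, mean
    differences), smoothed cross-site temporal patterns, singular value
    decomposition based temporal trend extraction from incomplete panels, a
    simplified single-trend spatiotemporal exposure model with
    leave-one-site-out cross-validation, an explicit rule set for choosing
    among candidate modeling approaches, and a synthetic-data generator
    emulating the networks' sampling designs and measurement
    inconsistencies so the whole pipeline is testable without proprietary
    data.
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
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
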