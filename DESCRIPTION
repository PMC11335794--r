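Package: statmon
Title: Statistical Monitoring of Key Risk Indicators in Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A risk-based-monitoring analytics engine for clinical trials.
    Ingests subject-level trial domain data (demographics, adverse events,
    labs, protocol deviations, queries, form entry, disposition) from
    several source dialects via configurable column mappings, computes
    twelve key risk indicators per site (or country, or custom subset),
    scores each group with an overdispersion-adjusted z-statistic (with
    Fisher exact and Poisson regression alternatives), flags groups that
    cross configurable red/amber thresholds, and emits machine-readable
    exports and a self-contained HTML report. A bundled synthetic-trial
    simulator with controllable site heterogeneity and injectable at-risk
    sites makes the whole pipeline testable without external data.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
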