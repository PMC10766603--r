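Package: trawlr
Title: Standardize and Flag Bottom-Trawl Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to standardize haul-level scientific bottom-trawl survey
    tables and trim them to a stable spatio-temporal footprint and a
    consistently identified taxon list. Reads delimited survey tables, applies
    haul quality filters (gear, geolocation, date, effort), harmonizes taxonomy
    against a local backbone with survey-specific aliases, computes swept area
    and standardized catch rates (CPUE per hour, CPUA per square kilometre),
    reconstructs weights from abundance-at-length, and computes two flag
    families: temporal taxonomic-consistency flags (presence in fewer than 95
    percent of sampled years with fewer than four presence transitions) and
    spatio-temporal footprint flags (equal-area hexagonal cell-year
    completeness at two resolutions and two missing thresholds, plus a
    BioTIME-style rectangular grid rule). A synthetic survey generator with
    known ground truth supports recovery testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
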