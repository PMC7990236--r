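Package: riverN
Title: Semi-Distributed Watershed Nitrogen Box Model for Alpine Catchments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coupled hydrology/nitrogen mass-balance box model for
    snowmelt-dominated mountain watersheds. Tracks nitrate, ammonium and
    dissolved organic nitrogen through stream, vadose-zone and groundwater
    pools in routed sub-watersheds, driven by hourly hydrologic forcing.
    Sources include atmospheric wet and dry deposition, nitrogen-rich shale
    weathering, plant litter turnover, cattle excretion and biological
    fixation; sinks and transformations include Monod plant uptake,
    nitrification, net mineralization, denitrification and downstream
    export. Provides a synthetic forcing generator emulating snowmelt and
    monsoon hydrology, fourth-order Runge-Kutta integration with a full
    flux ledger, six packaged calibration scenarios for equifinality
    exploration, and annual source/sink budget machinery including the
    geogenic ("new" nitrogen) decomposition.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
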