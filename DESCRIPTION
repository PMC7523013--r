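Package: olfnav
Title: Olfactory-Navigation Analysis of Homing-Pigeon Tracks, Air-Mass
    Trajectories and VOC Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis linking homing-pigeon GPS
    tracks to regional volatile-organic-compound (VOC) gradients and air-mass
    transport. Computes per-bird homing indices (initial mean vectors,
    deviation from west, the homing efficiency index HEI, the mean aggregate
    azimuth penalty MAAP, endpoint distance); parses HYSPLIT trajectory
    endpoint files and classifies hourly air-parcel positions into
    marine-boundary-layer, land and above-boundary-layer residence to form
    sea:land ratios; builds 16-direction by 6-speed-class wind profiles and
    the west wind component (WWC); summarises VOC time series as diel cycles
    and bivariate polar (wind direction by wind speed) maps; and converts OH
    rate constants into atmospheric lifetimes and e-folding transport
    distances. Seeded generators simulate a coastal sea-breeze system,
    direction-dependent VOC sources, back-trajectories over a land/sea mask
    and homeward-biased correlated-random-walk flights, so the whole pipeline
    is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
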