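Package: emscover
Title: Dynamic Isochrone Coverage Indicators for Emergency Medical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event simulation of a rural Emergency Medical System
    (EMS) hub and its ambulances on a grid road network, with a family of
    dynamic isochrone-based public-health indicators: time-weighted population
    coverage within k minutes (phi_k), per-town time coverage (pi_k), and
    ambulance occupation fractions. Travel times respond to weather penalties,
    accident congestion, road-closure days and a stress multiplier; accidents
    arrive as per-road monthly Poisson processes and the served population
    varies with weekends, local events and hotel stays. Ships a fully
    reconstructed Avila (Spain) 2014 scenario on a synthetic radial network, a
    random-scenario generator for property testing, deployment sweeps over the
    number of staffed ambulances with common random numbers, CSV/GeoJSON
    exporters, and ggplot2 visualisations.
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
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
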