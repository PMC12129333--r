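Package: luxtrack
Title: Light-Level Geolocation and Migration Analysis for Archival Tags
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing archival light-logger (geolocator) data from
    migratory birds using the threshold method: twilight extraction from raw
    light logs, clock-drift correction, change-point segmentation of twilight
    series into stationary periods and migration legs, sun-elevation-angle
    calibration at a known site, threshold geolocation with equinox and
    polar-day handling, per-leg migration event tables with site
    classification and phenology, and population-level movement statistics
    (migratory spread with randomization confidence intervals, minimum convex
    polygon range overlap, loop-migration contrasts, flight-time and fuel
    budgets). Includes a synthetic-track simulator that generates twilight
    series with one-sided shading noise and ground-truth labels for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
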