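Package: actispace
Title: Context-Specific Physical Activity from Combined Accelerometer and GPS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying where and when young
    children accumulate physical activity from paired hip-worn accelerometer
    and GPS logger data. Classifies 10-second epochs into intensity classes
    with rescalable count cut-points, detects non-wear from low-variability
    raw-signal windows, cleans GPS fixes and segments them into transport
    trips with pause handling and 90th-percentile-speed mode classification,
    infers home anchors from early-morning fixes, assigns each fix to
    integrated home-school distance categories and buffered public-space
    polygons, applies valid-day criteria, and aggregates day-level spatial,
    trip and temporal activity summaries. A synthetic-cohort generator
    produces ground-truth-labelled child-days so the full pipeline can be
    exercised and validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
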