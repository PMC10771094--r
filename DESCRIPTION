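Package: batcage
Title: Flight-Cage Bioassays of Bat Responses to Ultrasonic Deterrents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-bat flight-cage trials of ultrasonic deterrent
    emissions, renders the trials through virtual side-view thermal cameras,
    recovers per-frame detections by background subtraction with a
    spatiotemporal neighbor filter, converts pixels to distance from the
    deterrent via per-camera monotone calibrations with multi-camera fusion,
    and estimates species-, sex- and season-resolved quantile treatment
    effects of the emissions with cluster-bootstrap uncertainty, control
    consistency checks, and factorial analysis of variance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    tiff,
    car,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
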