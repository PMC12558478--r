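Package: facdamage
Title: Health Facility Damage Assessment from Remote-Sensing Building
    Damage Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts building-level damage outputs from satellite-imagery
    models into post-disaster health facility damage reports. Two building
    damage dialects are supported: footprint polygons carrying a damaged
    fraction, and building centroid points carrying a binary damage class.
    Facilities are classified either individually (point-in-polygon overlay
    with a 25 m nearest-damaged-centroid rescue) or through spatial
    aggregation on a fixed-area hexagonal grid with quartile thresholding.
    An evaluation layer computes inter-model agreement (Cohen's kappa) and
    accuracy against gold-standard labels (sensitivity and specificity with
    exact Clopper-Pearson intervals), overall and stratified by facility
    type and city. A synthetic-city generator reproduces the documented
    error structure of such models (polygon merging, multi-centroid
    assignment, destroyed-building misses, geocoding offsets) so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
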