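Package: flywayr
Title: Identifying Common Long-Distance Movement Routes of Nomadic Waterbirds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising common long-distance
    movement routes ("flyways") of nomadic waterbirds from GPS telemetry.
    Builds species-specific 24-hour displacement-line series from tracking
    tables, classifies daily movements with hidden Markov models (gamma step
    lengths, von Mises turning angles) selected by AIC, demarcates core
    routes as 50% kernel utilization-distribution contours, characterises
    routes against terrain-flatness, elevation and rainfall rasters with
    chi-square use-versus-availability comparisons, and stratifies routes by
    wet and dry water years. Includes a synthetic trajectory and environment
    generator so the full pipeline can be exercised and tested without
    external tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
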