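Package: vineyield
Title: Unsupervised Grape Cluster Detection and Yield Estimation from
    Canopy RGB Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects grape clusters (bunches) in high-resolution RGB
    images of the vine fruiting zone and turns detected cluster area into
    a pre-harvest yield estimate.  The pipeline converts sRGB rasters to
    CIELAB, smooths the blue-yellow opponent channel (b*), removes
    vegetation with a first Otsu threshold, isolates clusters with a
    second Otsu threshold on the remaining pixels, measures connected
    components with calibrated area/perimeter/circularity morphometry,
    applies area and circularity filters plus a double-cluster count
    adjustment, and fits a linear cluster-area to cluster-weight
    regression for season-transfer yield prediction.  Includes detection
    and accuracy metrics (TPR, TPR on ripe clusters, percent error,
    percent accuracy, NDVI), a ground-versus-UAV survey cost calculator,
    and a seeded synthetic vineyard-scene generator with per-pixel ground
    truth so every stage is testable without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
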