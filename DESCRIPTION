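Package: phenoflux
Title: Linking Previous-Season Temperature and Carbon Uptake to Spring Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for analysing how temperature and
    photosynthetic carbon assimilation during the previous growing season
    relate to the current year's start of season (SOS). Provides phenology
    extraction from three families of seasonal time series (satellite
    vegetation index via Savitzky-Golay smoothing and double-logistic
    fitting with second-derivative transition dates; camera green chromatic
    coordinate via a 50%-amplitude threshold; eddy-covariance gross primary
    productivity via singular spectrum analysis smoothing and a 15%
    threshold), record-screening filters (MAD outlier fencing, bare-land
    NDVI masking, record-length rules), site-level climate metrics
    (growing-season means, normalized anomalies, chilling and forcing
    units, bilinear interpolation from gridded climate), temperature
    sensitivity and partial-correlation statistics, a piecewise structural
    equation model with Fisher's C d-separation test, random-forest
    variable importance, and a synthetic multi-site data generator with
    fully known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
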