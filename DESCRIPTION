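Package: riparianSDM
Title: Temporally Explicit Habitat-Suitability Modelling for Riparian Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for temporally explicit species distribution modelling in
    Mediterranean-climate stream networks. Computes windowed hydrologic metrics
    (flashiness, recession rate, hydroperiod, storm and drought events, flow
    magnitudes) from daily streamflow over 3-, 5-, 10-year and full-record
    horizons aligned to species observations; fits a regional weekly
    stream-temperature regression and derives annual temperature metrics;
    clusters species by categorical traits with Gower dissimilarity for
    focal-species selection; fits dual-driver species distribution models
    (random forest on flow metrics with vote-fraction probabilities, and
    PCA-reduced logistic regression on temperature metrics); and projects
    end-of-century habitat-suitability change, elevation-stratified and
    limiting-variable summaries. Ships a synthetic-data generator with known
    ground truth (linear-reservoir hydrology, planted logistic occurrence
    responses) so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
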