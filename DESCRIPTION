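Package: pfsdiag
Title: Population-Based Farm Survey Diagnostics of Soil Nutrient Limitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing yield-limiting soil nutrients in smallholder
    agroecosystems from population-based farm survey data. Implements the Land
    Degradation Surveillance Framework (LDSF) hierarchical sampling design with
    Y-frame plot geometry, a synthetic-data generator with spatially correlated
    nutrient surfaces and known ground truth, partial least squares calibration
    of mid-infrared spectra with Savitzky-Golay preprocessing and hold-out
    cross-validation, Cate-Nelson calibration of localized critical soil-test
    values, frequency-overlap cut-off derivation, DRIS (Diagnosis and
    Recommendation Integrated System) nutrient-balance indices and limitation
    ranking, inverse-distance-weighted interpolation maps, and Moran's I
    spatial autocorrelation with Monte Carlo permutation tests. A configurable
    pipeline orchestrates the four-step survey -> diagnose -> rank -> map
    workflow with reproducible seeding and machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
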