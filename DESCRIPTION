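Package: accelspec
Title: Physical Activity Intensity Spectrum Analysis from Raw Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes raw tri-axial accelerometer recordings into a physical
    activity intensity spectrum under two frequency-filter configurations (an
    ActiGraph-emulating 1.6 Hz low-pass band and a wide 10 Hz band), applies
    night-time removal, non-wear detection and valid-day rules, derives a
    standardized six-marker cardiometabolic composite score, and relates the
    spectrum to the composite score by partial least squares regression with
    target projection, signed selectivity ratios and Monte Carlo resampling
    for component selection and confidence intervals. Includes a synthetic
    cohort generator with known ground truth so the whole pipeline is
    testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
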