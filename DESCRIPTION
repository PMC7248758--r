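Package: aquagrams
Title: Classic and Temperature-Based Aquagrams for Water NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aquaphotomics analysis of near-infrared water spectra in
    the first overtone region (1300-1600 nm). Implements the classic aquagram
    (multiplicative-scatter-corrected, per-wavelength standardized absorbance at
    the 12 water matrix coordinates, WAMACs) and the temperature-based aquagram,
    which expresses any perturbation of the water spectral pattern as the
    equivalent temperature change in degrees Celsius via a local calibration
    against a pure-water temperature series. Includes spectral pretreatments
    (MSC, SNV, Savitzky-Golay derivatives, PCA), bootstrap percentile confidence
    intervals, radar-chart rendering, a synthetic water-spectra simulator for
    method validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
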