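Package: teafluor
Title: Multi-Channel LED-Induced Fluorescence Simulation and Tea Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-channel LED-induced fluorescence measurements of
    tea leaves (seven UV-to-blue excitation LEDs plus a background frame on a
    200-1100 nm spectrometer grid), applies the standard chemometric
    pre-processing chain (background subtraction, Savitzky-Golay smoothing,
    chlorophyll-peak normalization, truncation to the 500-900 nm window) to
    form 7 x 837 excitation-emission matrices, and classifies the nine tea
    classes with a from-scratch convolutional neural network as well as
    PCA plus k-nearest-neighbor baselines (per-LED, concatenated-spectra and
    concatenated-component variants). Includes a full evaluation harness,
    spectral CSV input/output and a YAML-configured pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    withr,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
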