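Package: featimg
Title: Quantitative EEG Z-Score Feature Images for Dementia Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multichannel resting-state EEG into age- and sex-standardized
    Z-score spectra against a normative database, rearranges the 19-channel 10-20
    montage spectra into a single rectangular feature matrix integrating spatial and
    spectral information, and renders it as feature images (nearest, bicubic,
    weight-map and band-rescaled variants). Includes a synthetic EEG generator for
    normative cohorts and Alzheimer's-dementia-like spectral profiles, a compact
    convolutional network classifier with residual blocks trained from scratch, a
    band-aligned local surrogate explainer that recovers band-level classification
    criteria, and a kernel-density-intersection score cutoff.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
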