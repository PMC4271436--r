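Package: multiapod
Title: Non-Linear Multi-Apodization Beamforming for High-Frequency Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesis and evaluation of the minimum-selection dual-/tri-apodization
    scheme for side-lobe suppression in high-frequency (40 MHz) linear-array
    B-mode ultrasound imaging. Provides closed-form rectangular, Dolph-Chebyshev
    and Kaiser apodization windows with padded-DFT spectral measurements
    (main-lobe width in bins, highest side-lobe level), a point-scatterer RF
    channel-data simulator for a focused 128-element array, delay-and-sum
    receive beamforming with dynamic focusing and pluggable receive apodization,
    envelope detection, log compression, and image-quality metrics (lateral beam
    projections, main-lobe widths in micrometers, side-lobe region-of-interest
    levels, and contrast-to-noise ratio of anechoic cyst phantoms).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
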