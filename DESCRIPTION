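Package: ledhsi
Title: Simulation and Analysis of LED-Based Wavelength-Scanning Hyperspectral Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulator and processing chain for a wavelength-scanning
    hyperspectral imaging (HSI) instrument built from a multiwavelength LED array
    and a monochrome camera. Models an 18-channel LED illuminator (405-910 nm),
    sequential single-LED frame acquisition with configurable pulse width and
    inter-channel delay, and a noisy camera forward model (shot, read and dark
    noise with quantization). Implements flat-field calibration against dark and
    white-reference captures, histogram-based segmentation of hyperintense
    background and glare, rigid image alignment with mask-overlap region-of-interest
    construction, spectral-signature extraction with min-max normalization,
    signal-to-noise-ratio estimation in dB, and per-band one-tailed two-sample
    t-tests between tissue groups. Closed-form calculators for hypercube
    acquisition rate, required camera frame rate, wireless-link throughput, pixel
    pitch and field of view are included, together with ENVI and multi-page TIFF
    hypercube I/O, CSV signature export and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    withr,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
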