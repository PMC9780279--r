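Package: retinacuity
Title: Spatial Resolution of Artificial Retinal Stimulation from RGC Population Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to infer the spatial resolution of electrical and optogenetic
    retinal stimulation from retinal ganglion cell (RGC) population spiking.
    Includes a synthetic generator of MEA-like recordings with modality-specific
    stimulation artifacts, the matching preprocessing filter chains and
    sensor-reset drift removal, unit curation and per-phase firing-rate
    analysis with the relative-firing-rate (RFR) selectivity index and a
    Hartigan dip test of its distribution, cross-validated support-vector
    decoding of grating phase, and assembly of f1-versus-bar-width acuity
    curves with conversion to cycles per degree.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
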