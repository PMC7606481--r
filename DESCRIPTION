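Package: angioperf
Title: Perfusion Angiography from Digital Subtraction Angiography Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolution-free perfusion analysis for 2D digital subtraction
    angiography (DSA) frame sequences. Tracks the contrast bolus per pixel to
    derive arrival time (AT), time-to-peak (TTP), time-to-drain (TTD), mean
    transit time (MTT, full width at half maximum), relative cerebral blood
    volume (CBV, integral ratio against a manually placed arterial input
    function) and cerebral blood flow (CBF = CBV/MTT, central volume
    principle). Provides quality-control checks for pre/post intervention
    study pairs, vascular-territory distribution statistics with Welch
    pre/post comparison, jointly normalized colorized parametric maps, a
    gamma-variate digital flow phantom with dense-grid ground-truth kinetics,
    and DICOM/TIFF/PNG input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
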