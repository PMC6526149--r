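Package: flownmr
Title: Compact-NMR Process Monitoring, NIR Calibration Transfer, and
    Economic Real-Time Optimization for Continuous Reactors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative evaluation of low-field (43 MHz) flow NMR spectra
    by Indirect Hard Modeling (constrained superposition of pseudo-Voigt
    pure-component models) with one-point absolute calibration,
    steady-state detection in concentration time series, calibration
    transfer to an online NIR spectrometer by partial least squares
    regression with standard normal variate preprocessing, and economic
    real-time optimization by modifier adaptation with quadratic
    approximation (MAWQA).  Includes a virtual continuous lithiation
    reactor (1:1:2 stoichiometry with a moisture side sink) that forward
    synthesizes NMR and NIR spectra so the whole monitoring and control
    chain can be exercised without plant data.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
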