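Package: asapscreen
Title: Screening of Anabolic Steroid Esters by Multi-Voltage In-Source
    Fragmentation Library Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open implementation of a compact ASAP-MS (atmospheric solids
    analysis probe, single quadrupole) screening workflow for anabolic steroid
    esters in oily injection preparations. Builds four-cone-voltage (12, 20,
    30, 40 V) in-source-fragmentation reference libraries in NIST MSP text
    format, matches unknown multi-channel spectra with a 0-1000 cosine score
    and conjunctive hit criteria, confirms hits against selected-ion-recording
    (SIR) chronograms, and computes method-performance statistics (matrix
    effect, method limit of detection from peak-to-peak signal-to-noise,
    relative standard deviation, linearity, false-positive and false-negative
    rates). A seeded synthetic-acquisition generator emulates the
    voltage-dependent fragmentation, mixture additivity, oil-matrix
    interference, detector saturation and chronogram geometry the workflow
    assumes, so every stage is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
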