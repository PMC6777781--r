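Package: echosim
Title: Adaptive Staircase Simulation and Click Acoustics for Human
    Echolocation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse automated human-echolocation
    detection experiments. Implements a single-interval adjustment-matrix
    (SIAM) yes-no staircase with reversal-based threshold estimation,
    random and signal-detection-theory response models, Monte Carlo
    calibration of chance-level performance, participant-level session
    statistics, and a synthetic click-acoustics generator with a running
    1-ms windowed sound pressure level analysis that extracts direct and
    reflected click levels and inter-click intervals as a function of
    reflector distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
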