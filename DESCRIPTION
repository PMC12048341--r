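Package: opmr
Title: Encoding and Decoding of On-Patient Medical Records in Microneedle
    Bit Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for storing small medical payloads as two-dimensional
    binary microneedle-patch patterns read out by near-infrared
    fluorescence imaging. Implements Reed-Muller error-correcting codes
    with majority-logic decoding, grid templates with corner orientation
    markers, XOR encryption masks, a synthetic fluorescence image
    simulator with longitudinal signal-degradation tiers, classical image
    processing for binarization, minimum-area-rectangle rectification and
    grid bit recognition, and an end-to-end encode/decode pipeline with
    evaluation and signal-retention analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
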