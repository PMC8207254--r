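Package: wristsleep
Title: Wrist-Temperature and Actigraphy Sleep Rhythm Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sleep and circadian rhythm from wrist-worn
    sensors. Cleans and smooths distal skin (wrist) temperature series,
    computes nonparametric circadian indices (interday stability, intraday
    variability), single-component cosinor parameters (MESOR, amplitude,
    acrophase) and sleep/wake temperature contrast; identifies sleep periods
    from tri-axial accelerometry and reconstructs nightly sleep journals from
    partially completed caregiver observation sheets; quantifies agreement
    between device-reported and reference sleep with absolute differences,
    valid-day summaries and group statistics. Includes a synthetic
    wearable-data generator with three sleeper phenotypes (quiet, periodic
    in-sleep movement, fragmented sleep) so every stage can be exercised
    end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
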