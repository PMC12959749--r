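Package: vowelspace
Title: Acoustic Vowel Space Metrics and Intelligibility-Gain Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes acoustic vowel space metrics from tabulated F1/F2 formant
    measurements and relates their change over time to speech-intelligibility
    gain. Implements the articulatory-acoustic vowel space (AAVS, the square
    root of the generalised variance of F1/F2), the quadrilateral corner-vowel
    area (qVSA), and the convex-hull vowel space area (VSAhull); derives
    pre/post change scores; and fits an ordinary least squares model of
    intelligibility gain on the three change scores with variance inflation
    factor and residual diagnostics. Includes a synthetic speaker-cohort
    generator emulating a two-session, ten-vowel /hVt/ elicitation design for
    validation and power exploration, plus vowel-space plotting utilities
    (group overlays, formant shift arrows, per-vowel confidence ellipses).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    jsonlite,
    lmtest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
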