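Package: atdose
Title: Internal Alpha-Emitter Dosimetry and Transcriptional Response Profiling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for normal-tissue transcriptional responses to
    internally administered alpha-emitting radionuclides such as astatine-211.
    Computes organ mean absorbed doses from time-activity curves with the MIRD
    formalism (trapezoidal cumulated activity, alpha-only energy deposition,
    absorbed fraction 1), calls differentially expressed transcripts per
    exposure condition from normalized log2 expression matrices (Welch tests
    with Benjamini-Hochberg control), screens for dose-rate-sensitive
    biomarker genes regulated at all exposure conditions with direct/inverse/
    mixed pattern classification, and builds GO-based cellular-function
    response profiles with binned intensity levels. A seeded synthetic-data
    generator emulates the underlying animal/microarray study design so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
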