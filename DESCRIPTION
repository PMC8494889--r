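Package: sncascreen
Title: Reporter Cell Line Drug-Screen Analysis for Modulators of SNCA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for a luciferase reporter cell-line
    high-throughput drug screen targeting alpha-synuclein (SNCA)
    transcription. Provides per-plate control normalization and hit calling
    with a symmetric cutoff at a multiple of the untreated-control
    fold-change standard deviation, resazurin and live/dead-count viability
    classification, efficiency-corrected relative qPCR quantification with
    multiple reference genes (Pfaffl method), loading- and
    vehicle-normalized protein quantification for In-Cell Western and
    Western blot, one-way ANOVA with Dunnett's many-to-one comparisons
    computed by numerical quadrature, a staged triage cascade with a
    counter-screen specificity filter, and a synthetic plate-data generator
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
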