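Package: mptsdt
Title: Discrete-State and Signal-Detection Measurement Models for
    Confidence-Rating Recognition Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting of multinomial processing tree (MPT)
    models and of the unequal-variance signal-detection (UVSDT) model to
    pooled 4-point confidence-rating recognition data.  Implements the
    two-high-threshold (2HTM) recognition model with lure-type-specific
    detection parameters, likelihood-ratio G-squared goodness-of-fit and
    nested-model tests, parametric bootstrap uncertainty, ratio
    (shrinkage-factor) reparametrizations for testing interactions across
    materials, reconstruction of pooled response counts from published
    proportion tables, and a synthetic-data generator emulating
    levels-of-processing false-memory experiments with category, colour and
    critical lures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
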