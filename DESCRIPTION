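Package: traitlm
Title: Trait-Conditioned Autoregressive Language Modeling via Per-Layer
    Key/Value Adapter Injection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Conditions a decoder-only autoregressive transformer language
    model on a vector of continuous psychological trait scores (standard
    deviations from a population mean) through lightweight per-layer learned
    projections that supply the key and value states of a prepended dummy
    position. Includes trait-vector algebra (focal-dimension construction,
    multi-trait combination, interpersonal-circumplex rotation), a
    participant-level linear trait estimator transferred to message level,
    a synthetic trait-conditioned corpus simulator with known ground truth,
    a blinded level-matching evaluation protocol with weighted Cohen's
    kappa, JSONL corpus I/O with social-media preprocessing filters, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
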