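Package: codagree
Title: Agreement Metrics and Non-Inferiority Testing for Automated
    Qualitative Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A blinded evaluation framework for comparing automated coders
    (such as large language models) against human analysts and an
    adjudicated reference standard in qualitative thematic coding.
    Implements chance-corrected agreement statistics (Cohen's kappa,
    Gwet's AC1) with segment-level bootstrap confidence intervals,
    one-sided non-inferiority and superiority tests for deductive
    (binary segment-by-code) and inductive (Likert-scale) coding tasks
    with Holm multiplicity control, a quote-verification audit that
    classifies model-emitted evidence quotes and computes strict,
    expanded and comprehensive error rates, and seeded simulators for
    every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
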