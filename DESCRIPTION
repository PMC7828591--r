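Package: stopnet
Title: Stop-Signal Race Simulation, N2 Difference-Wave Derivation, and
    Longitudinal Path Inference for Inhibitory Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying inhibitory control with the stop-signal
    task (SST) and event-related potentials (ERP), end to end on
    synthetic data.  Simulates SST sessions under the independent
    horse-race model with staircase tracking of the stop-signal delay;
    estimates the stop-signal reaction time (SSRT) by the integration
    method with go-omission replacement, including race-model validity
    screening; derives the stop-minus-slow-go difference wave and the
    N2 region-of-interest mean amplitude from epoched data, with
    split-half reliability; generates synthetic longitudinal cohorts
    from a target correlation matrix or a recursive path model; and
    fits the inferential chain used in longitudinal high-risk ADHD
    research: hierarchical regression, quartile ANCOVA with planned
    contrasts, recursive path analysis with Sobel indirect effects and
    covariance-structure fit indices, and multiple imputation with
    Rubin's rules pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
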