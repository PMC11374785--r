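Package: changeofmind
Title: Error-Correcting Responses in Conflict-Based Cognitive Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying change-of-mind (error-correcting) responses in
    conflict-based cognitive games. Simulates game sessions from evidence
    accumulation and independent-race models with the game's adaptive
    staircases; implements player- and trial-level data-quality rules;
    extracts reaction-time and stopping measures (RT1, RT2, time-to-stop,
    integration-method SSRT); fits hierarchical mixed models of conflict
    effects with CR2 cluster-robust inference and Satterthwaite degrees of
    freedom; and evaluates measurement reliability via even-odd split-half
    correlations, McDonald's omega, and bias-corrected accelerated (BCa)
    cluster bootstrap intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    boot
Config/testthat/edition: 3
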