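Package: sccproc
Title: Self-Concept Clarity Trajectories and Psychotherapy Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Process-outcome analysis of self-concept clarity (SCC) measured
    repeatedly during psychotherapy. Classifies individual SCC trajectories
    into five reliable-change shapes (monotonic increase, "V" shape,
    discontinuous change, plateau, monotonic decrease), quantifies SCC
    fluctuation as the root mean square error around a per-subject
    logarithmic trend, splits patients into four personality dispositions
    from baseline SCC and neurotic-personality cutoffs, and relates shapes
    and fluctuations to pre-post symptom change via likelihood-ratio G-tests
    on fourfold tables, an interaction regression, a two-factor ANOVA, and a
    three-level variance-components null model. Includes a synthetic cohort
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    car,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
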