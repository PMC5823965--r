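Package: stopERP
Title: Simulation and Analysis of Emotional Auditory Stop-Signal ERP Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing emotional stop-signal
    experiments with event-related potentials (ERPs). Provides an
    independent horse-race trial simulator with a one-up/one-down
    stop-signal-delay staircase, integration-method SSRT estimation, a
    synthetic 32-channel EEG generator with planted N1/P3/ERN/Pe component
    templates, overlap-equating per-delay equal-weight ERP averaging with
    amplitude and peak-latency scoring, and the statistical layer used in
    such studies: paired t tests with effect sizes, 2x2 repeated-measures
    ANOVA with partial eta squared, standardized multiple regression,
    dependent-correlation (Steiger) Z tests, Kolmogorov-Smirnov normality
    screening, Bonferroni correction and noncentral-t power for paired
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
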