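Package: ctcgamma
Title: Beta/Gamma Oscillation Analysis in Corticothalamic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for late (200-700 ms post-stimulus)
    sensory-induced beta and gamma oscillations in multi-site
    corticothalamic field-potential recordings (EEG, layer 6, VPm, PoM),
    contrasting a saline control with an NMDA-antagonist (ketamine)
    condition. Provides normalised band power, an evoked/induced power
    decomposition, band-limited multiscale sample entropy,
    magnitude-squared coherence between recording sites, and the
    accompanying statistical battery (paired t, Wilcoxon signed-rank,
    one- and two-way ANOVA with Holm-Sidak correction). Includes a seeded
    phenomenological generator of paired saline/ketamine sessions with
    slow-wave-sleep background, phase-locked evoked transients,
    random-phase induced bursts and a shared gamma source, so that every
    stage of the pipeline is testable without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
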