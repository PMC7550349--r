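Package: oflphys
Title: Psychophysiology Pipeline for Observational Fear Learning Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-phase observational fear
    learning (OFL) experiments with electrodermal and startle-EMG outcome
    measures. Generates constrained stimulus timelines (pseudo-random CS order,
    partial reinforcement, startle-probe placement), renders synthetic 2 kHz
    skin conductance and orbicularis-oculi EMG recordings with injectable
    condition effects, scores skin conductance responses (tonic/phasic
    decomposition, trough-to-peak amplitude, response floor, log
    normalization) and fear-potentiated startle (band-pass, rectify, smooth,
    windowed peak, T-scores), classifies contingency awareness from
    questionnaire answers, and runs the group-level statistics (paired t,
    repeated-measures and mixed ANOVA with Bonferroni post-hocs,
    Kruskal-Wallis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    car,
    data.table,
    signal,
    splines,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
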