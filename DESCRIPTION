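Package: flankdmc
Title: Conflict Diffusion Modelling of Flanker-Task Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, fitting and distributional analysis of the diffusion
    model for conflict tasks (DMC) applied to flanker-style experiments. The
    model superimposes a constant target drift on a pulse-like, gamma-shaped
    distractor drift in a single Wiener diffusion process. The package
    provides a trial-level simulator with deadline and fast-guess handling,
    G-squared fitting of RT-quantile and conditional-accuracy summaries by
    differential evolution, an eight-model BIC ladder over the conflict
    parameters, RT/accuracy delta functions with slope-intercept regression,
    synthetic cohort generation for parameter-recovery and power studies, and
    the standard behavioural statistics (congruency effects, paired tests,
    repeated-measures ANOVA, within-subject standard errors).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
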