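Package: respacer
Title: Adaptive Closed-Loop Respiratory Pacing Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: In-silico testbed for an adaptive pattern-generator/pattern-shaper
    (PG/PS) respiratory pacing controller driving diaphragm and external
    intercostal stimulation channels with periodic sigh insertion. Provides a
    synthetic respiratory plant (piecewise-linear recruitment, charge-driven
    muscle fatigue, first-order lung mechanics with inspiratory-muscle synergy,
    an intrinsic breathing oscillator with Hering-Breuer volume-triggered phase
    reset, and noisy breath-volume sensing), the full performance-metric suite
    (percent inspiratory RMSE, charge per cycle, fatigue index,
    entrainment/adaptation detection, sigh tidal volume factor, synchrony
    events, exact one-sided Wilcoxon signed-rank test), strength-duration curve
    simulation and Weiss-model fitting (rheobase, chronaxie), and a trial
    runner with text-based configuration, CSV/JSON trial records and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
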