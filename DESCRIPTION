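Package: reachadapt
Title: Adaptive Feedback Control and Trial-by-Trial Learning in Force-Field Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of planar reaching adaptation to
    velocity-dependent force fields cued by constant background loads. Provides
    a linear-quadratic-Gaussian (LQG) state-feedback simulator with online and
    trial-by-trial adaptation of the force-field estimate, generators for the
    experimental trial schedules, kinematic trial metrics (initial angle, path
    length), single- and dual-rate exponential decay fits with BIC model
    selection, Wald and participant-bootstrap confidence intervals, paired
    tests with a normal-approximation power formula, and random-intercept
    mixed models. A synthetic-cohort generator with known ground truth makes
    the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    signal,
    minpack.lm,
    lme4,
    lmerTest,
    Matrix,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
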