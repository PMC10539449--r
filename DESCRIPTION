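Package: vrracquet
Title: Simulation and Analysis of a Virtual-Reality Racquetball Interception Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying predictive sensorimotor control with a
    virtual-reality racquetball paradigm in which ball elasticity varies
    probabilistically over time. Provides a volatile trial-sequence
    generator with explicit probabilistic cues, a deterministic
    projectile-and-bounce physics model, a synthetic-participant generator
    (delta-rule belief updating with linear cue blending) that emits raw
    headset/controller motion and eye-gaze streams, pipelines that derive
    interception rate, peak swing velocity, range of motion and
    dispersion-based (I-DT) bounce-fixation metrics from those streams, and
    the inferential battery used on such data: two-by-two mixed ANOVAs with
    partial eta squared, Bonferroni post-hoc and Mann-Whitney follow-ups,
    trait correlations, assumption checks, JZS and BIC Bayes factors, and
    noncentral-F a-priori power calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    yaml,
    optparse
Config/testthat/edition: 3
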