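Package: prlerp
Title: Simulation and ERP Analysis of a Child Probabilistic Reward-Learning Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying probabilistic reward learning with
    event-related potentials (ERPs). Simulates a two-alternative
    (face versus house) probabilistic reward task with Win-Stay/Lose-Shift,
    Rescorla-Wagner and reference agents; synthesizes multichannel epoched
    EEG carrying condition-dependent components (reward positivity, P300,
    N2pc) on a geodesic-style 128-channel montage with 1/f, line-noise and
    blink contamination; and analyses behaviour (strategy proportions,
    learning curves, per-subject learning rates, good/poor learner split)
    and ERPs (resampling, Butterworth band-pass, bad-channel detection,
    mastoid re-referencing, baseline correction, trial-by-trial artifact
    rejection with spherical-spline interpolation, condition binning,
    difference waves, region-of-interest window means, and the
    contralateral-minus-ipsilateral N2pc), through to paired/independent
    t-tests and a mixed-design repeated-measures ANOVA with partial eta
    squared. Includes Monte-Carlo parameter-recovery and type-I-error
    calibration harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
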