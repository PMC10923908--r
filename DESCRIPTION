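Package: tmrtools
Title: Closed-Loop Targeted Memory Reactivation: Simulation and Analysis
    of Sleep EEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for closed-loop targeted
    memory reactivation (TMR) experiments during slow-wave sleep. Provides
    a synthetic sleep-EEG generator (slow oscillations, spindles, 1/f
    background, hypnogram and arousals), a replay simulator of online
    slow-oscillation trough detection with phase-targeted auditory cueing,
    offline phase validation with circular statistics, ERP and Morlet
    time-frequency analysis with cluster-based permutation inference,
    per-timepoint multivariate decoding of cue-evoked activity, the
    transitive-inference behavioural task (pair construction, learning-block
    scheduling, exit criterion, scoring), and brain-behaviour correlation
    with bootstrap inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
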