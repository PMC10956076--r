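Package: eitrack
Title: Model-Based Tracking of Cortical Excitation-Inhibition Balance from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-by-sample estimation of the excitation-inhibition (E/I)
    balance of cortical activity from single-channel EEG. A Jansen-Rit
    neural-mass model is fitted to the recording with a variational Bayesian
    noise-adaptive constrained ensemble Kalman filter (vbcEnKF) that jointly
    estimates the six model states and five physiological parameters under
    interval constraints while adapting the observation-noise scale online.
    The ratio of the estimated excitatory and inhibitory synaptic gains gives
    a time-resolved model-based E/I index, mE/I(t) = A/(A+B). Includes the
    synthetic-EEG generator used for validation, an ensemble-size benchmark
    study, the spectral 1/f-slope E/I baseline, and a sleep-stage statistics
    pipeline (Kruskal-Wallis and Dunn tests with rank-based effect sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
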