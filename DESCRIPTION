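Package: brainstates
Title: Brain-State Dynamics in Multichannel Rest Recordings via Gaussian Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level hidden Markov modelling of multichannel resting-state
    recordings with multivariate Gaussian observation models, aimed at
    eyes-open versus eyes-closed study designs. Provides variational-Bayes
    inference with a free-energy trace, Viterbi decoding, model selection by
    free energy, maximum fractional occupancy and repeat reliability, state
    metrics (fractional occupancy, lifetimes, intervals, switching rate) with
    paired condition contrasts and Bonferroni correction, sliding-window
    occupancy time courses with cross-modal correlation, EEG alpha-band
    feature extraction (bandpass, Hilbert envelope, Welch power), state-wise
    weighted multitaper spectra, double-gamma HRF regressor construction with
    multi-level GLM mapping, and a fully seeded synthetic study generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
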