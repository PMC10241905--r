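Package: pigeonflow
Title: Sleep-State fMRI Simulation, Scoring and BOLD-CSF Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sleep-state-dependent brain activation and
    ventricular cerebrospinal-fluid (CSF) inflow in the avian brain. Provides a
    forward simulator of resting-state fMRI sessions with a ground-truth
    hypnogram (semi-Markov NREM/REM/eye-open bout process, double-gamma
    hemodynamic response, through-slice CSF inflow model, video-actimetry
    traces, motion and respiration confounds); behavioral sleep scoring from
    actimetry with epoch occupancy and transition-discard rules; fMRI
    preprocessing (framewise displacement, motion censoring, in-mask smoothing,
    grand-mean scaling, discrete-cosine high-pass, respiratory-phase
    regressors); a first-level state general linear model with fixed-effects
    session combination and sign-flip permutation group inference (max-stat,
    TFCE, cluster modes); the BOLD-CSF cross-correlation statistic with a
    circular-shift permutation null, bout-locked averaging and ROI
    parameter-estimate comparisons; and multitaper EEG spectral analysis with
    stimulus-locked delta-power contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
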