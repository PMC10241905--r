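# pigeonflow

Sleep-state fMRI analysis for the avian brain: simulation, behavioral
scoring, preprocessing, state GLM, and BOLD–CSF coupling statistics.

## The problem

During sleep, the brain's blood-oxygen-level-dependent (BOLD) activity and
the flow of cerebrospinal fluid (CSF) through the ventricles are coupled:
when gray-matter BOLD falls (NREM sleep), fresh CSF flows into the imaging
volume and the ventricular signal at the edge slices rises; during REM
sleep the opposite happens. In pigeons, sleep alternates between many
short NREM and REM bouts per session (on the order of 85 NREM and 72 REM
bouts in an 80-minute scan, REM bouts typically shorter than 10 s), which
makes the bird an ideal system for studying this coupling — but also means
the whole analysis chain (behavioral scoring from video actimetry, motion
censoring, state regressors, lagged correlation statistics) has to handle
fast state dynamics correctly.

`pigeonflow` implements that chain end to end, driven by a synthetic
session generator with known ground truth, so every stage is verifiable
without any scanner data:

- **synthdata** — semi-Markov NREM/REM/eye-open bout process (gamma dwell
  times), double-gamma hemodynamic response, a linear slice-replacement
  model of the through-slice CSF inflow effect, video actimetry, motion
  spikes and respiration; everything composed into a 4D phantom.
- **scoring** — 1-s-epoch behavioral scoring (bilateral eye closure,
  iris/bill motion, the two-thirds eye-open rule), 100% epoch occupancy,
  2-s transition discard, bout statistics.
- **preprocess** — framewise displacement (FD) and censoring at 0.09 mm
  native scale, volume trimming, in-mask Gaussian smoothing, grand-mean
  scaling, discrete-cosine high-pass (0.01 Hz), respiratory-phase
  regressors, confound regression, voxelwise Z-scoring.
- **glm** — state regressors convolved with the hemodynamic response plus
  temporal derivatives, OLS with optional AR(1) prewhitening, t/z
  contrasts, fixed-effects session combination, and sign-flip permutation
  group inference with max-stat, TFCE, or cluster-extent FWE correction.
- **coupling** — the core statistic: the lagged Pearson cross-correlation
  `r(l) = cor(bold(t), csf(t + l))` on TR-step lags, its session-averaged
  curve, a circular-shift permutation null with a 95% band and two-sided
  p-value `(1 + k)/(n_perm + 1)`, the 12-s bout-isolation rule,
  bout-onset-locked averages, and paired/two-sample comparisons of ROI
  parameter estimates with Bonferroni correction.
- **eeg** — multitaper (Slepian-taper) spectrograms, stimulus-locked
  time–frequency averaging, and delta-band (0.5–4 Hz) power contrasts.

## Worked example

```r
library(pigeonflow)

ses <- generate_session(generator_config(), seed = 1)
ses
#> Synthetic session: 12x12x6 grid, 1200 volumes, TR 4.0 s
#>   156 bouts; seed 1

bout_statistics(ses$hypnogram)[1:2, 1:3]
#>   state count mean_duration
#> 1  NREM    78         53.73
#> 2   REM    66          6.72

gm  <- zscore_ts(extract_roi_mean(ses$volumes, ses$masks$gm))
csf <- zscore_ts(extract_roi_mean(ses$volumes, ses$masks$ivv_bottom))
coupling_perm_test(gm, csf, max_lag_s = 20, tr_s = 4,
                   n_perm = 1000, seed = 1)
#> BOLD-CSF coupling: peak r = -0.132 at +4 s lag (n = 1 session(s),
#> 1000 permutations, p = 0.001)
```

The session's gray-matter BOLD and ventricular CSF series are most
strongly (negatively) correlated when the CSF series is taken 4 s — one
TR — later than BOLD: CSF inflow follows the BOLD decrease. The
permutation p-value is the fraction of circularly shifted surrogates
whose lag-curve extremum reaches the observed one; `p = 0.001` is the
floor attainable with 1000 permutations, i.e. no surrogate reached it.

The same objects feed the rest of the pipeline: `score_epochs()` /
`epochs_to_bouts()` recover the hypnogram from the actimetry traces,
`build_design()` + `fit_glm()` + `glm_contrast()` test state contrasts
such as REM > NREM, `filter_isolated_bouts()` + `bout_locked_average()`
produce onset-locked time courses, and `run_pipeline()` executes
everything and writes a BIDS-like results directory. A thin command-line
front end is installed at `inst/cli/pigeonflow`.

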