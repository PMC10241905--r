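---
title: "Sleep-state BOLD-CSF coupling: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-state BOLD-CSF coupling: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigeonflow)
```

This vignette is the package's account of its science: what the forward
model generates and why, what the analysis estimates, which knobs matter,
and where the design was genuinely open.

## The phenomenon being modeled

In small birds, sleep fragments into many brief bouts: NREM episodes of a
few tens of seconds, REM episodes typically under 10 s, interrupted by
short uni- or bilateral eye openings. During NREM sleep gray-matter (GM)
BOLD activity falls while cerebrospinal fluid flows into the ventricles;
during REM sleep GM BOLD rises to wake-like levels and CSF inflow stops.
In an fMRI acquisition the inflow is visible as a signal increase in
ventricle voxels at the *edge slices* of the imaging volume: spins
flowing in have not yet experienced magnetization saturation, so a slice
whose CSF is partly replaced each TR is brighter than one at saturated
steady state. The analysis quantifies this coupling as the lagged
cross-correlation between a GM ROI mean and a bottom-slice ventricular
ROI mean, with the CSF series trailing the BOLD series by about one TR.

## The forward model

`generate_session()` composes five parts, all driven by one integer seed
through a splittable sub-seed scheme (`hypnogram`, `motion`,
`respiration`, `actimetry`, `noise` streams).

**Bout process.** A semi-Markov chain over
{NREM, REM, LEFT_OPEN, RIGHT_OPEN, BOTH_OPEN} in which REM is reachable
only from NREM. Dwell times are gamma-distributed (shape 2), redrawn
until at least 2 s — shorter bouts could never survive scoring at 1-s
epochs with a 2-s transition discard. Defaults were derived analytically
and then verified by simulation (`scripts/calibrate_generator.R`): with
the REM-entry probability p = 72/85 equating the REM/NREM bout-count
ratio, and mean dwells of 6 s (REM) and 20 s (eye-open), the NREM mean
dwell that yields ~85 NREM bouts per 80-minute session solves a
cycle-time equation at about 47.5 s. Simulated means over 1000 sessions
are 85.4 (NREM) and 71.7 (REM) without further adjustment.

**Hemodynamic response.** A double gamma, `pigeon_hrf()`: a shape-5
response gamma peaking at `peak_s` minus a sharper (shape-12) undershoot
gamma at `undershoot_s`, scaled by `undershoot_ratio` and normalized to
unit net area. The avian HRF's exact published shape is not reproduced
anywhere we can cite numerically, so these are package assumptions, not
literature values. The default peak of 2 s encodes that avian
hemodynamics are faster than mammalian; the sharp undershoot keeps the
argmax at the configured peak time by construction, which makes the
contract testable.

**CSF inflow.** `csf_inflow_signal()` is a linear slice-replacement
model: signal rises linearly with the replaced slice fraction
`v * TR / thickness` and clips at full replacement; velocity 0 returns
the saturated baseline. Richer multi-slice saturation physics is out of
scope. Per-state velocities (NREM 0.2, REM 0.02, eye-open 0.05 mm/s at
1-mm slices) are free parameters of the generator — true avian values are
unknown — chosen so NREM sits at 80% replacement and REM near baseline.

**Coupling timing.** The GM signal is the HRF-convolved state amplitude
boxcar. The CSF velocity drive passes through the *same* HRF and is then
delayed by `csf_delay_s` (default one TR, 4 s) before entering the inflow
model. Using the same kernel on both sides is deliberate: it makes the
noiseless cross-correlation extremum fall exactly at `csf_delay_s`, so
"+4 s" means *CSF follows BOLD by 4 s* — the interpretable, testable
convention. (Delaying the raw state boxcar instead would let the HRF's
own ~2-s lag cancel most of the configured delay, and the recovered lag
would no longer equal the parameter.) Physiologically this says that
neurovascular coupling drives both signals through common hemodynamics.

**Noise and confounds.** Each ROI compartment receives shared Gaussian
noise (`noise_sd_gm` 1.16, `noise_sd_csf` 0.63 Z units), every voxel
receives independent thermal noise (sd 0.5), all brain voxels share an
aliased respiratory modulation (0.5 Hz breathing sampled at TR 4 s) and
signal artifacts at motion-spike frames. Motion parameters are slow
jitter plus sparse persistent jumps (rate 0.002/volume) whose size always
exceeds the 0.09-mm censoring threshold, so ~0.2% of volumes are
censored. The two noise sds were calibrated once, jointly against two
prescribed behaviors: the 29-session mean cross-correlation peak near
-0.13, and single-session recovery of the +4-s lag in at least 19 of 20
seeds. Both constrain the same attenuation product; the second also needs
a sufficiently sharp clean lag curve, which the 2-s HRF provides. At this
operating point the per-session argmin is inherently noisy (about 92% of
sessions recover the lag exactly; the rest peak at 0 or 8 s), which is
why the session-averaged curve, not a single session, is the primary
statistic.

## Scoring rules

A state is attributed to a 1-s epoch only when its defining conditions
hold for every frame of the epoch; epochs matching zero definitions are
UNSCORED. An eye is open above aperture 2/3 and completely closed below
1/3; NREM requires bilateral closure with all motion channels at the
noise floor; REM requires bilateral closure with iris and/or bill motion
above threshold. Breathing is removed from the bill channel by an FFT
band-stop at the configured respiration rate ± 0.2 Hz (NREM permits bill
motion related to breathing). When epochs are merged into bouts, 2 s are
discarded at both ends of every run. Session edges are treated like state
changes — the state before recording onset is unknown — so even a
uniformly labeled session loses 2 s at each end; runs of 4 s or less
vanish entirely. Occupancy is applied before the discard. On generated
actimetry, scoring recovers 100% of epoch labels outside the discarded
transition zones; real video adds ambiguity (feather collapse, partial
apertures) that this generator does not emulate, so that figure is an
upper bound, not a claim about real data.

## Preprocessing

Framewise displacement is the translation sum plus head-radius-scaled
rotation sum of backward differences (radius 10 mm, native scale; the
scanner convention of 10x voxel upscaling makes the published 0.9-mm
threshold equal 0.09 mm here). Censored volumes become one-hot spike
regressors rather than deletions, preserving the time grid for lagged
analyses. The high-pass filter is a projection onto the complement of a
DCT-II basis spanning periods longer than 1/cutoff — unlike a Butterworth
filter this makes the contract exact: drifts inside the span are removed
completely, white noise loses exactly the basis-dimension fraction of its
variance in expectation. Grand-mean scaling targets 10000 by convention.
In-mask smoothing renormalizes the Gaussian kernel over in-mask voxels,
computed separably as the ratio of two ordinary convolutions, so no
signal bleeds across the mask edge. Respiratory-phase regressors are
volume-level cos/sin harmonics (default order 2) of a phase interpolated
between detected breath peaks; slice-level phases are out of scope.

## GLM and group inference

The first-level design holds one HRF-convolved boxcar per state present
in the hypnogram plus its first-difference temporal derivative, an
intercept, and unconvolved confounds. States without bouts simply lack
columns; contrasts referencing them raise an error, mirroring the
per-condition subject counts a real cohort would have. Fitting is OLS;
optional prewhitening estimates one AR(1) coefficient per voxel from the
residuals and refits once — a deliberate simplification of
locally regularized autocorrelation models. Sessions are combined by
inverse-variance-weighted fixed effects. Group inference is a one-sample
sign-flip permutation test with FWE control by the maximum statistic;
`tfce` mode applies threshold-free cluster enhancement (H = 2, E = 0.5,
6-connectivity, dh = max/100) and `cluster` mode uses maximum cluster
extent at a z > 2.3 forming threshold. The statistic is signed
(one-sided): the spec's exhaustive two-subject example (p in {1/4, 2/4,
3/4, 1}) is only attainable that way, since |t| is invariant to flipping
every sign. When the requested permutation count reaches 2^n_subjects the
test warns and enumerates all flips, and p becomes the exact fraction
k/2^n including the identity.

## The coupling statistic

`cross_correlation()` correlates `bold(t)` with `csf(t + l)` over the
overlapping window on TR-step lags; positive l means CSF later than BOLD.
`coupling_perm_test()` averages per-session curves with equal weights,
takes the extremum of |mean r| as the observed statistic, and builds the
null by circularly shifting each session's CSF series by a random offset
of at least 10 TR — shifts preserve autocorrelation, which naive sample
shuffling would destroy, and offsets are drawn without replacement while
the pool lasts. p = (1 + k)/(n_perm + 1) two-sided; the 95% band is the
pointwise 2.5/97.5 percentile of null mean curves. Known limitation: for
short series the test is mildly anticonservative (measured type-I ~0.065
at 150 samples, ~0.057 at 400, target 0.05) because null statistics at
nearby offsets are more inter-correlated with one another than with the
observed alignment; at the 1000+-volume session lengths the analysis
targets, the effect is within the calibration band. The bout-locked
window default is [-8, +20] s, and the 12-s isolation rule keeps a
NREM/REM bout only when no NREM/REM bout offset falls within 12 s before
its onset — under continuous NREM/REM alternation only bouts entered from
eye-open gaps qualify, so isolated bouts are rare by design. SEM in
bout-locked averages and lag curves is computed across bouts/sessions per
offset (not across lags).

## EEG spectral analysis

Multitaper spectrograms use Slepian tapers computed from the symmetric
tridiagonal eigenproblem (no external taper library), with
time-bandwidth product `window_s * bw_hz / 2`, so the default 4-s window
at 1-Hz bandwidth gives NW = 2 and admits k = 3 tapers (k <= 2NW - 1 is
enforced). Windows are zero-padded to the next power of two; the
one-sided estimate satisfies Parseval (integrated power ~ variance,
within 5% for white noise). Delta power is the mean over 0.5-4 Hz and a
time interval; the before/during-stimulation contrast is a per-bird
paired t-test, which with one value per bird per condition coincides
with a random-intercept mixed model in the balanced case.
`simulate_eeg_recording()` provides 1/f-plus-delta synthetic EEG for the
tests; it is a spectral phantom, not a biophysical model.

## Problem sizes and determinism

The shipped tests and the acceptance script use the study-scale problem
sizes where the target quantities demand them (1200-volume sessions, 29
sessions for the coupling curve, 1000 hypnograms for bout counts, 5000
permutations for the p-value floor) and reduced sizes (250-volume
sessions, 100-400 Monte-Carlo replicates, 99-500 permutations) for
property checks whose validity does not depend on scale. All randomness
descends from explicit integer seeds; the full pipeline is deterministic
given its seed, and the preprocessing stages are deterministic outright.

## What passing tests do and do not show

The generator reproduces the *statistical structure* the analysis
assumes: bout architecture, hemodynamic lag, inflow saturation, noise
levels calibrated to the published effect size. It does not emulate
pigeon neuroanatomy, k-space physics, nonlinear registration residuals,
scanner drift beyond the DCT span, or real video artifacts. Green tests
therefore certify the *estimators* — that the pipeline recovers known
ground truth under realistic noise — not the biological claims, which
require the original scanner data.
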