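#' Configuration for the synthetic-session generator
#'
#' Bundles every knob of the forward model: acquisition constants (TR 4 s,
#' 1200 volumes, i.e. an 80-minute session), the semi-Markov bout process,
#' the hemodynamic response, per-state gray-matter (GM) BOLD amplitudes and
#' CSF inflow velocities, the CSF-behind-BOLD coupling delay (default one
#' TR), noise levels, respiration, motion spikes, and the phantom grid.
#'
#' Dwell-time and transition defaults are calibrated once (see
#' `scripts/calibrate_generator.R` in the source tree) so that the mean
#' per-session bout counts are about 85 NREM and 72 REM, with REM bouts
#' typically shorter than 10 s. Noise standard deviations are calibrated by
#' the same script so the 29-session mean BOLD-CSF cross-correlation peaks
#' near -0.13.
#'
#' @param tr_s Repetition time, seconds.
#' @param n_volumes Number of volumes per session.
#' @param state_dwell Named list of `c(mean=, shape=)` gamma dwell
#'   parameters (seconds) per state.
#' @param state_probs Named list of named transition-weight vectors; rows
#'   are normalized, REM must only be reachable from NREM.
#' @param hrf_params `c(peak_s=, undershoot_s=, undershoot_ratio=)` for the
#'   double-gamma hemodynamic response.
#' @param bold_amp Named per-state GM BOLD amplitude (Z units).
#' @param csf_velocity Named per-state mean CSF inflow velocity (mm/s).
#' @param csf_delay_s Delay of the CSF response behind the GM BOLD signal,
#'   seconds; an integer multiple of `tr_s` by default.
#' @param slice_thickness_mm Acquisition slice thickness for the inflow model.
#' @param coupling_gain Scalar multiplying both the GM amplitudes and the
#'   CSF inflow dynamic range (correlation-preserving signal gain).
#' @param noise_sd_gm,noise_sd_csf ROI-level noise standard deviation
#'   (Z units) added to the GM and CSF compartment signals.
#' @param voxel_noise_sd Independent per-voxel thermal noise (Z units).
#' @param resp_rate_hz Respiration rate (avian, ~0.5 Hz).
#' @param resp_amp Amplitude of the aliased respiratory modulation added to
#'   brain voxels (Z units).
#' @param motion_spike_rate Per-volume probability of a motion spike.
#' @param motion_spike_sd_mm Scale of spike displacements (native mm).
#' @param video_fps Actimetry video frame rate.
#' @param grid_dim 3D phantom grid dimensions (voxels).
#' @param voxel_mm Isotropic voxel size, mm (native scale).
#' @param seed Optional default seed recorded in the config.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(tr_s = 4, n_volumes = 1200,
                             state_dwell = NULL, state_probs = NULL,
                             hrf_params = c(peak_s = 2, undershoot_s = 7,
                                            undershoot_ratio = 0.15),
                             bold_amp = c(NREM = -0.8, REM = 0.8,
                                          LEFT_OPEN = 0, RIGHT_OPEN = 0,
                                          BOTH_OPEN = 0),
                             csf_velocity = c(NREM = 0.2, REM = 0.02,
                                              LEFT_OPEN = 0.05,
                                              RIGHT_OPEN = 0.05,
                                              BOTH_OPEN = 0.05),
                             csf_delay_s = 4, slice_thickness_mm = 1,
                             coupling_gain = 1,
                             noise_sd_gm = 1.16, noise_sd_csf = 0.63,
                             voxel_noise_sd = 0.5,
                             resp_rate_hz = 0.5, resp_amp = 0.05,
                             motion_spike_rate = 0.002,
                             motion_spike_sd_mm = 0.3,
                             video_fps = 30,
                             grid_dim = c(12L, 12L, 6L), voxel_mm = 1,
                             seed = NULL) {
  if (is.null(state_dwell)) {
    state_dwell <- list(
      NREM       = c(mean = 47.5, shape = 2),
      REM        = c(mean = 6,    shape = 2),
      LEFT_OPEN  = c(mean = 20,   shape = 2),
      RIGHT_OPEN = c(mean = 20,   shape = 2),
      BOTH_OPEN  = c(mean = 20,   shape = 2))
  }
  if (is.null(state_probs)) {
    state_probs <- list(
      NREM       = c(REM = 0.847, LEFT_OPEN = 0.051, RIGHT_OPEN = 0.051,
                     BOTH_OPEN = 0.051),
      REM        = c(NREM = 1),
      LEFT_OPEN  = c(NREM = 1),
      RIGHT_OPEN = c(NREM = 1),
      BOTH_OPEN  = c(NREM = 1))
  }
  cfg <- list(tr_s = tr_s, n_volumes = n_volumes, state_dwell = state_dwell,
              state_probs = state_probs, hrf_params = hrf_params,
              bold_amp = bold_amp, csf_velocity = csf_velocity,
              csf_delay_s = csf_delay_s,
              slice_thickness_mm = slice_thickness_mm,
              coupling_gain = coupling_gain,
              noise_sd_gm = noise_sd_gm, noise_sd_csf = noise_sd_csf,
              voxel_noise_sd = voxel_noise_sd,
              resp_rate_hz = resp_rate_hz, resp_amp = resp_amp,
              motion_spike_rate = motion_spike_rate,
              motion_spike_sd_mm = motion_spike_sd_mm,
              video_fps = video_fps, grid_dim = as.integer(grid_dim),
              voxel_mm = voxel_mm, seed = seed)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (!inherits(cfg, "generator_config")) stopf("not a generator_config")
  if (cfg$tr_s <= 0) stopf("tr_s must be > 0")
  if (cfg$n_volumes < 2) stopf("n_volumes must be >= 2")
  for (s in names(cfg$state_dwell)) {
    if (cfg$state_dwell[[s]][["mean"]] <= 0) stopf("dwell mean for %s <= 0", s)
  }
  if (!all(is.finite(unlist(cfg$bold_amp)))) stopf("bold_amp must be finite")
  if (any(unlist(cfg$csf_velocity) < 0)) stopf("csf_velocity must be >= 0")
  if (cfg$motion_spike_rate < 0 || cfg$motion_spike_rate > 1) {
    stopf("motion_spike_rate must lie in [0, 1]")
  }
  if (cfg$slice_thickness_mm <= 0) stopf("slice_thickness_mm must be > 0")
  if (cfg$hrf_params[["peak_s"]] <= 0) stopf("hrf peak time must be > 0")
  for (s in names(cfg$state_probs)) {
    tgt <- names(cfg$state_probs[[s]])
    if ("REM" %in% tgt && s != "NREM" && cfg$state_probs[[s]][["REM"]] > 0) {
      stopf("REM may only be entered from NREM")
    }
  }
  cfg
}

#' Double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with shape 5, parameterized by the
#' peak time, undershoot time and undershoot ratio, and normalized so the
#' net area under the curve is 1. The response is 0 at t = 0 and has a
#' single positive peak near `peak_s`. The avian HRF's exact shape is not
#' published; these are package defaults documented as assumptions.
#'
#' @param t Non-negative, increasing time grid (seconds).
#' @param hrf_params `c(peak_s=, undershoot_s=, undershoot_ratio=)`.
#' @return Amplitude at each `t` (1/seconds, unit area).
#' @export
pigeon_hrf <- function(t, hrf_params = generator_config()$hrf_params) {
  p <- hrf_params[["peak_s"]]
  u <- hrf_params[["undershoot_s"]]
  r <- hrf_params[["undershoot_ratio"]]
  if (p <= 0) stopf("hrf peak time must be > 0")
  if (any(t < 0)) stopf("t must be non-negative")
  if (is.unsorted(t)) stopf("t must be increasing")
  ## response gamma: shape 5 peaking at p; undershoot gamma: sharper
  ## (shape 12) so its density is negligible at the response peak and
  ## the argmax stays at the configured peak time
  h <- stats::dgamma(t, shape = 5, scale = p / 4) -
    r * stats::dgamma(t, shape = 12, scale = u / 11)
  h / (1 - r)  # each gamma has unit area, so net area is 1 - r
}

#' Through-slice CSF inflow signal model
#'
#' Linear slice-replacement model of the inflow effect: spins flowing into
#' an edge slice have not experienced magnetization saturation, so the
#' slice signal rises with the fraction of the slice replaced per TR,
#' `v * TR / thickness`, clipped at full replacement. At zero velocity the
#' signal equals the saturated steady-state baseline; at or beyond full
#' replacement it equals the fresh-spin maximum.
#'
#' @param velocity Non-negative inflow velocities (mm/s).
#' @param slice_thickness_mm Slice thickness (mm), > 0.
#' @param tr_s Repetition time (seconds).
#' @param s_sat Saturated baseline signal (default 0).
#' @param s_fresh Fresh-spin signal (default 1).
#' @return Signal series on the `[s_sat, s_fresh]` scale.
#' @export
csf_inflow_signal <- function(velocity, slice_thickness_mm, tr_s,
                              s_sat = 0, s_fresh = 1) {
  if (slice_thickness_mm <= 0) stopf("slice_thickness_mm must be > 0")
  if (any(velocity < 0)) stopf("velocities must be >= 0")
  frac <- pmin(velocity * tr_s / slice_thickness_mm, 1)
  s_sat + (s_fresh - s_sat) * frac
}

## Occupancy-weighted per-state indicator on a fine time grid.
## Returns a length(times) numeric of the quantity `value[state]`.
state_drive <- function(hyp, times, value, fill = 0) {
  st <- state_at(hyp, times)
  out <- rep(fill, length(times))
  known <- st %in% names(value)
  out[known] <- unname(value[st[known]])
  out
}

## Convolve a fine-grid drive with the HRF and sample at volume times.
## Both the BOLD signal and the CSF velocity drive pass through this, so
## the hemodynamic lag is common to the two and the configured coupling
## delay is exactly the lag of peak cross-correlation.
hrf_convolve <- function(drive, dt, hrf_params) {
  tk <- seq(0, 32, by = dt)
  k <- pigeon_hrf(tk, hrf_params)
  full <- stats::convolve(drive, rev(k), type = "open") * dt
  full[seq_along(drive)]
}

#' Clean per-volume GM BOLD and CSF inflow series for a hypnogram
#'
#' @param hyp A [hypnogram()].
#' @param config A [generator_config()].
#' @param dt Fine integration step (seconds).
#' @return list(gm, csf): numeric series of length `n_volumes`.
#' @keywords internal
clean_session_signals <- function(hyp, config, dt = 0.1) {
  n <- config$n_volumes
  tr <- config$tr_s
  tfine <- seq(0, n * tr - dt, by = dt)
  amp <- state_drive(hyp, tfine, config$bold_amp)
  vel <- state_drive(hyp, tfine, config$csf_velocity)
  gm_fine <- hrf_convolve(amp, dt, config$hrf_params) * config$coupling_gain
  vel_smooth <- hrf_convolve(vel, dt, config$hrf_params)
  ## delay the smoothed velocity drive: CSF follows BOLD by csf_delay_s
  lag_n <- round(config$csf_delay_s / dt)
  vel_del <- c(rep(vel_smooth[1], lag_n),
               vel_smooth[seq_len(length(vel_smooth) - lag_n)])
  csf_fine <- csf_inflow_signal(pmax(vel_del, 0), config$slice_thickness_mm,
                                tr) * config$coupling_gain
  tvol <- (seq_len(n) - 0.5) * tr
  idx <- pmin(round(tvol / dt) + 1, length(tfine))
  list(gm = gm_fine[idx], csf = csf_fine[idx])
}

## Phantom ROI masks on the generator grid. The CSF (fourth-ventricle
## bottom, "ivv_bottom") mask sits in the bottom slice where the inflow
## effect is strongest; the cerebellar recess ("cr") is adjacent and
## excluded from the CSF ROI; the GM mask is a 6.5-mm-diameter sphere with
## the left/right entopallium spheres inside it.
make_masks <- function(grid_dim, voxel_mm) {
  d <- grid_dim
  sphere <- function(center, radius_mm) {
    x <- (seq_len(d[1]) - center[1]) * voxel_mm
    y <- (seq_len(d[2]) - center[2]) * voxel_mm
    z <- (seq_len(d[3]) - center[3]) * voxel_mm
    r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
    r2 <= radius_mm^2
  }
  ctr <- c(ceiling(d[1] / 2), ceiling(d[2] / 2), max(d[3] - 1L, 1L))
  ivv <- array(FALSE, d)
  ivv[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 1):(ctr[2] + 1), 1] <- TRUE
  cr <- array(FALSE, d)
  cr[(ctr[1] - 1):(ctr[1] + 1), min(ctr[2] + 2, d[2]), 1:min(2, d[3])] <- TRUE
  ## telencephalic GM sphere; ventricular compartments are carved out
  gm <- sphere(ctr, 3.25) & !ivv & !cr
  ento_l <- sphere(ctr + c(-1.5, 0, 0), 1.1) & gm
  ento_r <- sphere(ctr + c(1.5, 0, 0), 1.1) & gm
  brain <- sphere(c(ctr[1], ctr[2], (d[3] + 1) / 2), 0.5 * max(d) * voxel_mm)
  brain <- brain | gm | ivv | cr
  if (!any(gm) || !any(ivv)) stopf("grid too small to contain the ROI masks")
  if (any(ivv & cr) || any(ivv & gm)) stopf("ROI masks overlap")
  list(gm = gm, ivv_bottom = ivv, cr = cr, ento_l = ento_l, ento_r = ento_r,
       brain = brain)
}

#' Generate actimetry traces for a hypnogram
#'
#' Emulates the video-derived movement signals used for behavioral sleep
#' scoring: eye apertures in \[0,1\], iris motion, and bill motion. During
#' NREM both eyes are closed and all motion sits at the noise floor, with
#' a breathing oscillation on the bill channel; during REM the eyes stay
#' closed but the irises (and bill, via breathing) show motion bursts;
#' during eye-open states the corresponding aperture exceeds two thirds.
#'
#' @param hyp A [hypnogram()].
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return An object of class `"actimetry"`: list with `fps` and a
#'   data.frame `channels` (left_eye_aperture, right_eye_aperture,
#'   left_iris_motion, right_iris_motion, bill_motion).
#' @export
generate_actimetry <- function(hyp, config = generator_config(), seed = NULL) {
  fps <- config$video_fps
  n <- round(hyp$session_length * fps)
  tt <- (seq_len(n) - 0.5) / fps
  st <- state_at(hyp, tt, fill = "NREM")
  local_seed(seed, {
    clip01 <- function(x) pmin(pmax(x, 0), 1)
    la <- clip01(abs(stats::rnorm(n, 0, 0.01)))
    ra <- clip01(abs(stats::rnorm(n, 0, 0.01)))
    open_l <- st %in% c("LEFT_OPEN", "BOTH_OPEN")
    open_r <- st %in% c("RIGHT_OPEN", "BOTH_OPEN")
    la[open_l] <- clip01(0.9 + stats::rnorm(sum(open_l), 0, 0.02))
    ra[open_r] <- clip01(0.9 + stats::rnorm(sum(open_r), 0, 0.02))
    ## iris motion: noise floor everywhere, exponential bursts during REM
    il <- stats::runif(n, 0, 0.3)
    ir <- stats::runif(n, 0, 0.3)
    rem <- st == "REM"
    il[rem] <- stats::rexp(sum(rem), rate = 0.5)
    ir[rem] <- stats::rexp(sum(rem), rate = 0.5)
    ## bill: breathing oscillation plus a small noise floor
    bill <- 2 * (0.5 + 0.5 * sin(2 * pi * config$resp_rate_hz * tt)) +
      stats::runif(n, 0, 0.1)
    structure(list(fps = fps,
                   channels = data.frame(left_eye_aperture = la,
                                         right_eye_aperture = ra,
                                         left_iris_motion = il,
                                         right_iris_motion = ir,
                                         bill_motion = bill)),
              class = "actimetry")
  })
}

## Per-volume motion parameters: slow jitter plus sparse persistent jumps
## (spikes) that produce isolated high-FD frames.
generate_motion <- function(config, seed = NULL) {
  n <- config$n_volumes
  local_seed(seed, {
    jit <- matrix(stats::rnorm(n * 6, 0, 0.003), n, 6)
    m <- apply(jit, 2, cumsum) * 0.2  # slow wander, well below threshold
    spikes <- which(stats::runif(n - 1) < config$motion_spike_rate) + 1L
    for (s in spikes) {
      ax <- sample(1:3, 1)
      jump <- sample(c(-1, 1), 1) *
        config$motion_spike_sd_mm * (0.5 + abs(stats::rnorm(1)))
      m[s:n, ax] <- m[s:n, ax] + jump
    }
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m[, 4:6] <- m[, 4:6] * 0.01  # radians, small
    m
  })
}

generate_respiration <- function(config, seed = NULL, fs = 20) {
  L <- config$tr_s * config$n_volumes
  tt <- seq(0, L - 1 / fs, by = 1 / fs)
  local_seed(seed, {
    rate <- config$resp_rate_hz * (1 + 0.05 * sin(2 * pi * tt / 97))
    phase <- 2 * pi * cumsum(rate) / fs
    list(fs = fs, trace = sin(phase) + stats::rnorm(length(tt), 0, 0.05),
         phase = phase, t = tt)
  })
}

#' Generate a complete synthetic resting-state session
#'
#' Forward model composing the bout process, hemodynamics, CSF inflow,
#' actimetry, motion and respiration into a 4D phantom with ground truth:
#' GM BOLD is the HRF-convolved state amplitude series (REM above NREM);
#' the CSF inflow signal is high in NREM and low in REM/eye-open states
#' and follows the BOLD signal by `csf_delay_s`, so the clean series are
#' anticorrelated at that delay. Compartment signals are painted into the
#' ROI masks with shared compartment noise, independent voxel noise,
#' aliased respiratory modulation and motion-spike artifacts.
#'
#' @param config A [generator_config()].
#' @param seed Integer master seed; every sub-draw derives from it.
#' @return An object of class `"synthetic_session"`: list with `volumes`
#'   (4D array x,y,z,t), `voxel_mm`, `tr_s`, `masks`, `hypnogram`,
#'   `actimetry`, `motion`, `respiration`, `truth` (clean `gm`, `csf`),
#'   `config`, `seed`.
#' @export
generate_session <- function(config = generator_config(), seed = NULL) {
  config <- validate_generator_config(config)
  hyp <- generate_hypnogram(config, derive_seed(seed, 1))
  clean <- clean_session_signals(hyp, config)
  masks <- make_masks(config$grid_dim, config$voxel_mm)
  n <- config$n_volumes
  motion <- generate_motion(config, derive_seed(seed, 2))
  resp <- generate_respiration(config, derive_seed(seed, 3))
  acti <- generate_actimetry(hyp, config, derive_seed(seed, 4))

  tvol <- (seq_len(n) - 0.5) * config$tr_s
  resp_mod <- config$resp_amp *
    sin(stats::approx(resp$t, resp$phase, xout = tvol, rule = 2)$y)
  ## signal artifacts only at spike frames (ordinary jitter is handled
  ## by the motion confounds, not painted into the data)
  fd <- framewise_displacement(motion)
  artifact <- ifelse(
    fd > 0.09, 0.3 * pmin(fd / max(config$motion_spike_sd_mm, 1e-9), 2), 0)

  nv <- prod(config$grid_dim)
  local_seed(derive_seed(seed, 5), {
    gm_roi <- clean$gm + stats::rnorm(n, 0, config$noise_sd_gm)
    csf_roi <- clean$csf + stats::rnorm(n, 0, config$noise_sd_csf)
    cr_roi <- 0.5 * clean$csf + stats::rnorm(n, 0, config$noise_sd_csf)
    vol <- matrix(stats::rnorm(nv * n, 0, config$voxel_noise_sd), nv, n)
    base <- numeric(nv)
    base[as.vector(masks$brain)] <- 90
    base[as.vector(masks$gm)] <- 100
    base[as.vector(masks$ivv_bottom)] <- 80
    base[as.vector(masks$cr)] <- 80
    vol <- vol + base
    bvox <- as.vector(masks$brain)
    vol[bvox, ] <- vol[bvox, ] +
      rep(resp_mod + artifact, each = sum(bvox))
    add_sig <- function(maskvec, sig) {
      vol[maskvec, ] <<- vol[maskvec, ] + rep(sig, each = sum(maskvec))
    }
    add_sig(as.vector(masks$gm), gm_roi)
    add_sig(as.vector(masks$ivv_bottom), csf_roi)
    add_sig(as.vector(masks$cr), cr_roi)
    dim(vol) <- c(config$grid_dim, n)
    structure(list(volumes = vol, voxel_mm = config$voxel_mm,
                   tr_s = config$tr_s,
                   masks = masks[c("gm", "ivv_bottom", "cr",
                                   "ento_l", "ento_r")],
                   hypnogram = hyp, actimetry = acti, motion = motion,
                   respiration = resp[c("fs", "trace")],
                   truth = list(gm = clean$gm, csf = clean$csf),
                   config = config, seed = seed),
              class = "synthetic_session")
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("Synthetic session: %dx%dx%d grid, %d volumes, TR %.1f s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  cat(sprintf("  %d bouts; seed %s\n", nrow(x$hypnogram$bouts),
              x$seed %||% "NULL"))
  invisible(x)
}
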