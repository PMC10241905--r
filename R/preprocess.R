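#' Framewise displacement from motion parameters
#'
#' FD(t) = sum of absolute backward differences of the three translations
#' (mm) plus `head_radius_mm` times the summed absolute rotation
#' differences (radians converted to arc length). FD of the first volume
#' is defined as 0.
#'
#' The scanner convention upscales voxels by a factor of 10, so the
#' published 0.9 mm threshold equals 0.09 mm at the native scale used
#' here; `head_radius_mm` defaults to 10 mm (native).
#'
#' @param motion n x 6 matrix: 3 translations (mm), 3 rotations (radians).
#' @param head_radius_mm Radius used to convert rotations to arc length.
#' @return Non-negative numeric vector of length n.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 10) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stopf("motion must have 6 columns, got %d",
                               ncol(motion))
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion censoring by framewise displacement
#'
#' Volumes with FD strictly above the threshold are censored; each gets a
#' one-hot spike regressor column so the time grid is preserved for lagged
#' analyses (censored volumes are regressed, not deleted).
#'
#' @param fd FD series from [framewise_displacement()].
#' @param threshold_mm Censoring threshold (strict inequality), > 0.
#' @return list(censored = integer indices, spikes = n x k one-hot matrix
#'   with one column per censored volume; 0 columns when none).
#' @export
censor_frames <- function(fd, threshold_mm = 0.09) {
  if (threshold_mm <= 0) stopf("threshold must be > 0")
  idx <- which(fd > threshold_mm)
  spikes <- matrix(0, length(fd), length(idx))
  if (length(idx)) {
    spikes[cbind(idx, seq_along(idx))] <- 1
    colnames(spikes) <- paste0("spike_", idx)
  }
  list(censored = idx, spikes = spikes)
}

#' Discard initial and final volumes
#'
#' Drops the first and last `n_first`/`n_last` time points (volumes) to
#' avoid pre-steady-state magnetization and temporal-filter edge effects.
#' Works on vectors, time-by-column matrices, and 4D arrays (time last).
#'
#' @param series Vector, matrix (time in rows), or 4D array (x,y,z,t).
#' @param n_first,n_last Number of volumes to discard at each end.
#' @return Trimmed object of the same kind.
#' @export
trim_volumes <- function(series, n_first = 5, n_last = 5) {
  pick <- function(n) {
    if (n <= n_first + n_last) stopf("series too short to trim")
    (n_first + 1):(n - n_last)
  }
  if (is.null(dim(series))) return(series[pick(length(series))])
  nd <- length(dim(series))
  if (nd == 2) return(series[pick(nrow(series)), , drop = FALSE])
  if (nd == 4) {
    return(series[, , , pick(dim(series)[4]), drop = FALSE])
  }
  stopf("series must be a vector, matrix, or 4D array")
}

## 1D Gaussian convolution along one axis of a 3D array, via a banded
## matrix product (kernel truncated at 3 sigma).
conv_axis <- function(arr, sigma_vox, axis) {
  d <- dim(arr)
  n <- d[axis]
  if (sigma_vox <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = sigma_vox)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    lo <- max(1, j - r); hi <- min(n, j + r)
    A[lo:hi, j] <- k[(lo:hi) - j + r + 1]
  }
  perm <- c(axis, setdiff(seq_len(3), axis))
  x <- aperm(arr, perm)
  dim(x) <- c(n, prod(d[-axis]))
  y <- crossprod(A, x)
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

gauss3d <- function(arr, sigma_vox) {
  for (ax in 1:3) arr <- conv_axis(arr, sigma_vox, ax)
  arr
}

#' Gaussian smoothing restricted to a mask
#'
#' Smooths with a Gaussian kernel (sigma = FWHM / 2.3548) whose weights
#' are renormalized over in-mask voxels only, so no signal bleeds across
#' the mask edge; voxels outside the mask are returned unchanged.
#'
#' @param volumes 3D array or 4D array (x,y,z,t).
#' @param mask Logical 3D array.
#' @param fwhm_mm Kernel full width at half maximum, mm.
#' @param voxel_mm Isotropic voxel size, mm.
#' @return Smoothed array of the same shape.
#' @export
smooth_in_mask <- function(volumes, mask, fwhm_mm = 8, voxel_mm = 1) {
  sigma <- fwhm_mm / 2.3548 / voxel_mm
  m <- array(as.numeric(mask), dim(mask))
  den <- gauss3d(m, sigma)
  one_vol <- function(v) {
    num <- gauss3d(v * m, sigma)
    out <- v
    out[mask] <- num[mask] / den[mask]
    out
  }
  if (length(dim(volumes)) == 3) return(one_vol(volumes))
  out <- volumes
  for (t in seq_len(dim(volumes)[4])) {
    out[, , , t] <- one_vol(volumes[, , , t])
  }
  out
}

#' Grand-mean scaling
#'
#' Global intensity normalization by a single multiplicative factor per
#' run: the 4D mean over in-mask voxels becomes `target` (10000, the FSL
#' convention). The factor is attached as attribute `"gm_factor"` so it
#' can be written to a sidecar and inverted.
#'
#' @param volumes 4D array.
#' @param mask Logical 3D array (default: all voxels).
#' @param target Target grand mean, > 0.
#' @return Scaled array with attribute `gm_factor`.
#' @export
grand_mean_scale <- function(volumes, mask = NULL, target = 10000) {
  if (target <= 0) stopf("target must be > 0")
  if (is.null(mask)) mask <- array(TRUE, dim(volumes)[1:3])
  vmat <- matrix(volumes, prod(dim(volumes)[1:3]), dim(volumes)[4])
  gm <- mean(vmat[as.vector(mask), ])
  if (gm <= 0) stopf("in-mask grand mean must be > 0")
  f <- target / gm
  out <- volumes * f
  attr(out, "gm_factor") <- f
  out
}

#' High-pass filtering by discrete-cosine projection
#'
#' Projects the series onto the orthogonal complement of a DCT-II basis
#' spanning all periods longer than `1/cutoff_hz` (plus the constant), so
#' slow drifts are removed exactly and the output has mean 0. The basis
#' dimension is `floor(2 * n * tr_s * cutoff_hz)` including the constant.
#'
#' @param ts Numeric vector or time-by-voxel matrix.
#' @param cutoff_hz High-pass cutoff, Hz.
#' @param tr_s Sampling interval, seconds.
#' @return Filtered series, same shape; attribute `"dct_dim"` gives the
#'   number of regressors projected out (including the constant).
#' @export
highpass_dct <- function(ts, cutoff_hz = 0.01, tr_s = 4) {
  x <- as.matrix(ts)
  n <- nrow(x)
  K <- max(0L, ceiling(2 * n * tr_s * cutoff_hz) - 1L)
  K <- min(K, n - 1L)
  t_i <- seq_len(n) - 0.5
  B <- cbind(1, if (K > 0) {
    sapply(seq_len(K), function(k) cos(pi * k * t_i / n))
  })
  res <- stats::lm.fit(B, x)$residuals
  out <- if (is.null(dim(ts))) as.vector(res) else res
  attr(out, "dct_dim") <- K + 1L
  out
}

#' Respiratory phase regressors (volume-level)
#'
#' Detects breath peaks in the respiration trace, assigns a phase
#' advancing linearly from 0 to 2*pi between successive peaks, samples it
#' at the volume acquisition times and returns cos/sin harmonics, in the
#' style of physiological-noise-model (RETROICOR) regressors. Slice-wise
#' offsets are out of scope; phases are volume-level.
#'
#' @param respiration Numeric trace.
#' @param fs Sampling rate, Hz (>= 10).
#' @param volume_times Acquisition time of each volume, seconds.
#' @param order Number of harmonics (default 2).
#' @return Matrix with columns `resp_cos1, resp_sin1, ...`.
#' @export
respiratory_phase_regressors <- function(respiration, fs, volume_times,
                                         order = 2) {
  if (fs < 10) stopf("respiration must be sampled at >= 10 Hz")
  pk <- pracma::findpeaks(respiration, minpeakheight = mean(respiration),
                          minpeakdistance = max(1, round(fs * 0.4)))
  if (is.null(pk) || nrow(pk) < 2) stopf("no peaks found in respiration trace")
  pk_t <- (sort(pk[, 2]) - 1) / fs  # sample i is at time (i-1)/fs
  ## linear phase between peaks; extrapolate with the edge cycle lengths
  cyc <- diff(pk_t)
  t0 <- pk_t[1] - cyc[1]
  tn <- pk_t[length(pk_t)] + cyc[length(cyc)]
  knots <- c(t0, pk_t, tn)
  phase_u <- stats::approx(knots, seq_along(knots) - 1, xout = volume_times,
                           rule = 2)$y
  phi <- 2 * pi * phase_u
  out <- do.call(cbind, lapply(seq_len(order), function(k) {
    cbind(cos(k * phi), sin(k * phi))
  }))
  colnames(out) <- as.vector(t(outer(seq_len(order), c("cos", "sin"),
                                     function(k, f) paste0("resp_", f, k))))
  out
}

#' Regress confounds out of a time series
#'
#' Ordinary least-squares residualization against the confound columns
#' (plus an intercept): the residual is orthogonal to every confound.
#'
#' @param ts Numeric vector or time-by-voxel matrix.
#' @param confounds Numeric matrix of per-volume confound columns.
#' @return Residual series, same shape as `ts`.
#' @export
confound_regress <- function(ts, confounds) {
  x <- as.matrix(ts)
  X <- cbind(intercept = 1, as.matrix(confounds))
  if (nrow(X) != nrow(x)) stopf("confounds and series lengths differ")
  res <- stats::lm.fit(X, x)$residuals
  if (is.null(dim(ts))) as.vector(res) else res
}

#' Z-score a time series
#'
#' Population convention: mean 0, standard deviation 1 with the 1/n
#' variance estimator. A constant series is an error.
#'
#' @param ts Numeric vector.
#' @return Z-scored vector.
#' @export
zscore_ts <- function(ts) {
  m <- mean(ts)
  s <- sqrt(mean((ts - m)^2))
  if (s == 0) stopf("cannot z-score a constant series")
  (ts - m) / s
}
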