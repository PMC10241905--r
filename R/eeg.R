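## Cache for DPSS tapers (the tridiagonal eigenproblem is not free).
.pf_dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, as the leading eigenvectors of the standard symmetric
#' tridiagonal commuting matrix. Tapers are unit-norm and mutually
#' orthogonal; signs are fixed so each taper has non-negative mean (even
#' orders) or a positive initial slope.
#'
#' @param n Taper length, samples.
#' @param nw Time-bandwidth product (`n * W` with `W` the half-bandwidth
#'   in cycles per sample).
#' @param k Number of tapers; must satisfy `k <= 2 * nw - 1`.
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k > 2 * nw - 1) {
    stopf("k = %d exceeds 2*NW - 1 = %g well-concentrated tapers",
          k, 2 * nw - 1)
  }
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.pf_dpss_cache[[key]])) return(.pf_dpss_cache[[key]])
  W <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  diag_off <- (seq_len(n - 1) * (n - seq_len(n - 1))) / 2
  M <- diag(diag_main)
  M[cbind(seq_len(n - 1), 2:n)] <- diag_off
  M[cbind(2:n, seq_len(n - 1))] <- diag_off
  ev <- eigen(M, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    flip <- if (abs(s) > 1e-10) sign(s) else sign(V[2, j] - V[1, j])
    V[, j] <- V[, j] * flip
  }
  .pf_dpss_cache[[key]] <- V
  V
}

#' Multitaper spectrogram of an EEG channel
#'
#' Sliding-window multitaper spectral estimate: per window, the average
#' of `k` orthonormal Slepian-tapered periodograms, with time-bandwidth
#' product `window_s * bw_hz / 2` (so `bw_hz` is the full analysis
#' bandwidth). Windows are zero-padded to the next power of two. The
#' estimate is one-sided and satisfies Parseval: the power integrated
#' over frequency approximates the signal variance per window.
#'
#' @param x Numeric EEG trace (microvolts).
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds (default 4).
#' @param step_s Window step, seconds (default 0.05).
#' @param bw_hz Analysis bandwidth, Hz (default 1).
#' @param k Number of tapers (default 3).
#' @param fmax Highest frequency retained, Hz (default 40).
#' @return Object of class `"spectrogram"`: `times` (window centers, s),
#'   `freqs` (Hz), `power` (time x freq, uV^2/Hz), plus the parameters.
#' @export
multitaper_spectrogram <- function(x, fs, window_s = 4, step_s = 0.05,
                                   bw_hz = 1, k = 3, fmax = 40) {
  if (fs <= 2 * fmax) stopf("fs must exceed 2 * fmax")
  n <- round(window_s * fs)
  if (length(x) < n) stopf("record shorter than one window")
  nw <- window_s * bw_hz / 2
  V <- dpss_tapers(n, nw, k)
  nfft <- 2^ceiling(log2(n))
  step <- max(1L, round(step_s * fs))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  nf <- nfft %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / nfft
  fsel <- freqs <= fmax
  P <- matrix(0, length(starts), sum(fsel))
  pad <- matrix(0, nfft - n, k)
  for (w in seq_along(starts)) {
    seg <- x[starts[w]:(starts[w] + n - 1L)]
    tap <- rbind(seg * V, pad)
    X <- stats::mvfft(tap)
    S <- rowMeans(abs(X[seq_len(nf), , drop = FALSE])^2) / fs
    S[2:(nf - 1)] <- 2 * S[2:(nf - 1)]  # one-sided
    P[w, ] <- S[fsel]
  }
  structure(list(times = (starts - 1 + n / 2) / fs, freqs = freqs[fsel],
                 power = P, fs = fs, window_s = window_s, step_s = step_s,
                 bw_hz = bw_hz, k = k),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("Spectrogram: %d windows x %d frequencies (0-%.1f Hz)\n",
              nrow(x$power), ncol(x$power), max(x$freqs)))
  invisible(x)
}

#' Stimulus-locked average time-frequency map
#'
#' Extracts a window of `window_s` seconds centered on each stimulus
#' onset from a spectrogram and averages the maps across trials on a
#' common offset grid. Trials whose window does not fit entirely inside
#' the spectrogram are dropped.
#'
#' @param spec A [multitaper_spectrogram()] result.
#' @param stim_onsets Stimulus onset times, seconds.
#' @param window_s Total window length centered on onset (default 40).
#' @return list(`offsets` (s, relative to onset), `freqs`, `power`
#'   (offset x freq mean map), `n_trials`).
#' @export
stim_locked_average <- function(spec, stim_onsets, window_s = 40) {
  half_n <- floor((window_s / 2) / spec$step_s)
  offs <- (-half_n):half_n
  maps <- list()
  for (on in stim_onsets) {
    i0 <- which.min(abs(spec$times - on))
    idx <- i0 + offs
    if (idx[1] < 1 || idx[length(idx)] > nrow(spec$power)) next
    maps[[length(maps) + 1]] <- spec$power[idx, , drop = FALSE]
  }
  if (!length(maps)) stopf("no stimulus window fits inside the spectrogram")
  avg <- Reduce(`+`, maps) / length(maps)
  list(offsets = offs * spec$step_s, freqs = spec$freqs, power = avg,
       n_trials = length(maps))
}

#' Average delta-band power
#'
#' Mean spectral power over a frequency band and time interval; the
#' default band is the delta band, 0.5-4 Hz.
#'
#' @param spec A [multitaper_spectrogram()] result, or a list with
#'   `times`/`offsets`, `freqs`, `power`.
#' @param band `c(lo, hi)` frequency band, Hz.
#' @param interval Optional `c(t0, t1)` time interval, seconds (on the
#'   map's own time axis); default the full extent.
#' @return Scalar mean power.
#' @export
delta_power <- function(spec, band = c(0.5, 4), interval = NULL) {
  times <- spec$times %||% spec$offsets
  fsel <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(fsel)) stopf("band outside the frequency grid")
  tsel <- if (is.null(interval)) rep(TRUE, length(times)) else {
    times >= interval[1] & times <= interval[2]
  }
  if (!any(tsel)) stopf("interval outside the time grid")
  mean(spec$power[tsel, fsel])
}

#' Paired comparison of delta power before vs during stimulation
#'
#' Per-bird paired t-test on mean delta power (one value per bird per
#' condition); with a balanced design this coincides with the random-
#' intercept linear mixed model on the same summaries.
#'
#' @param before,during Per-bird delta power values, equal length >= 2.
#' @return list(`t`, `dof`, `p`, `mean_diff` = mean(during - before)).
#' @export
delta_comparison <- function(before, during) {
  if (length(before) != length(during)) stopf("need paired values")
  if (length(before) < 2) stopf("need at least 2 birds")
  if (stats::sd(during - before) == 0) {
    d <- mean(during - before)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                dof = length(before) - 1,
                p = if (d == 0) 1 else 0, mean_diff = d))
  }
  ht <- stats::t.test(during, before, paired = TRUE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(during - before))
}

#' Simulate a synthetic EEG recording
#'
#' 1/f background plus a state-dependent delta-band (0.5-4 Hz)
#' oscillation: NREM-like segments carry a strong delta component that is
#' suppressed for `suppress_s` seconds after each stimulus onset
#' (awakening), wake-like segments carry little delta. Synthetic data for
#' testing the spectral pipeline; not a biophysical EEG model.
#'
#' @param duration_s Record length, seconds.
#' @param fs Sampling rate, Hz (default 256).
#' @param stim_onsets Stimulus onset times, seconds.
#' @param delta_amp Amplitude of the delta oscillation (uV).
#' @param suppress_s Post-stimulus delta suppression length, seconds.
#' @param seed Integer seed.
#' @return list(`x` (uV), `fs`, `stim_onsets`).
#' @export
simulate_eeg_recording <- function(duration_s, fs = 256,
                                   stim_onsets = numeric(0),
                                   delta_amp = 20, suppress_s = 20,
                                   seed = NULL) {
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  local_seed(seed, {
    ## 1/f background via spectral shaping of white noise
    wn <- stats::rnorm(n)
    X <- stats::fft(wn)
    f <- pmax(1 / duration_s, pmin((seq_len(n) - 1), n - (seq_len(n) - 1)) /
                duration_s)
    X <- X / sqrt(f)
    bg <- Re(stats::fft(X, inverse = TRUE)) / n
    bg <- 5 * bg / stats::sd(bg)
    delta_f <- 2 + 0.5 * sin(2 * pi * tt / 13)
    delta <- delta_amp * sin(2 * pi * cumsum(delta_f) / fs)
    gate <- rep(1, n)
    for (on in stim_onsets) {
      gate[tt >= on & tt < on + suppress_s] <- 0.1
    }
    list(x = bg + gate * delta, fs = fs, stim_onsets = stim_onsets)
  })
}
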