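test_that("framewise displacement matches the arc-length formula", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))
  m2 <- m; m2[4, 1] <- 1  # single 1-mm translation jump
  fd <- framewise_displacement(m2)
  expect_equal(fd[4], 1)
  expect_equal(fd[5], 1)  # the return to baseline also moves 1 mm
  expect_equal(fd[-c(4, 5)], rep(0, 8))
  m3 <- m; m3[6, 5] <- 0.01  # 0.01 rad at 10 mm radius -> 0.1 mm
  expect_equal(framewise_displacement(m3, head_radius_mm = 10)[6], 0.1)
  expect_error(framewise_displacement(m[, 1:5]), "6 columns")
})

test_that("censoring uses a strict threshold and one-hot spike columns", {
  cen <- censor_frames(c(0, 0.5, 1.0, 0.9), threshold_mm = 0.9)
  expect_equal(cen$censored, 3L)  # strictly above only
  expect_equal(dim(cen$spikes), c(4L, 1L))
  expect_equal(cen$spikes[, 1], c(0, 0, 1, 0))
  none <- censor_frames(rep(0, 5), 0.9)
  expect_equal(ncol(none$spikes), 0L)
  ## every spike column is one-hot
  cen2 <- censor_frames(c(1, 2, 0, 3), 0.5)
  expect_true(all(colSums(cen2$spikes) == 1))
  expect_error(censor_frames(c(0, 1), 0), "> 0")
})

test_that("volume trimming drops 5 + 5 and re-references onsets", {
  expect_length(trim_volumes(1:1200), 1190)
  expect_equal(trim_volumes(1:11), 6L)
  x4 <- array(seq_len(2 * 2 * 2 * 20), c(2, 2, 2, 20))
  expect_equal(dim(trim_volumes(x4))[4], 10)
  expect_error(trim_volumes(1:10), "too short")
  h <- toy_hypnogram(list("NREM", 20), list("REM", 10), list("NREM", 30))
  sh <- shift_hypnogram(h, 5 * 4)  # trim of 5 volumes at TR 4
  expect_equal(sh$bouts$onset[1], 0)
  expect_equal(sh$bouts$state[1], "REM")
})

test_that("in-mask smoothing preserves constants and respects the mask", {
  d <- c(9, 9, 5)
  mask <- array(FALSE, d); mask[3:7, 3:7, 2:4] <- TRUE
  img <- array(5, d)
  out <- smooth_in_mask(img, mask, fwhm_mm = 8, voxel_mm = 1)
  expect_equal(out, img, tolerance = 1e-10)  # constant stays constant
  ## impulse spreads as a kernel but never outside the mask
  img2 <- array(0, d); img2[5, 5, 3] <- 1
  bg <- array(rnorm(prod(d)), d); bg[mask] <- img2[mask]
  out2 <- smooth_in_mask(bg, mask, fwhm_mm = 4, voxel_mm = 1)
  expect_identical(out2[!mask], bg[!mask])
  expect_gt(out2[5, 5, 3], out2[3, 3, 2])
  expect_true(all(out2[mask] > 0))
  ## two-voxel mask: weights equal the hand-renormalized kernel
  m2 <- array(FALSE, d); m2[4, 5, 3] <- TRUE; m2[5, 5, 3] <- TRUE
  v <- array(0, d); v[4, 5, 3] <- 1; v[5, 5, 3] <- 3
  sigma <- 4 / 2.3548
  w0 <- dnorm(0, sd = sigma)^3
  w1 <- dnorm(1, sd = sigma) * dnorm(0, sd = sigma)^2
  out3 <- smooth_in_mask(v, m2, fwhm_mm = 4, voxel_mm = 1)
  expect_equal(out3[4, 5, 3], (w0 * 1 + w1 * 3) / (w0 + w1),
               tolerance = 1e-10)
  expect_equal(out3[5, 5, 3], (w0 * 3 + w1 * 1) / (w0 + w1),
               tolerance = 1e-10)
})

test_that("grand-mean scaling hits the target once and stays put", {
  vol <- array(5000 + rnorm(4 * 4 * 2 * 30), c(4, 4, 2, 30))
  s1 <- grand_mean_scale(vol)
  expect_equal(mean(s1), 10000, tolerance = 1e-10)
  expect_equal(attr(s1, "gm_factor"), 10000 / mean(vol))
  s2 <- grand_mean_scale(s1)
  expect_equal(unclass(s2), unclass(s1), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## factor round-trips through a sidecar value
  expect_equal(s1 / attr(s1, "gm_factor"), vol, ignore_attr = TRUE)
})

test_that("DCT high-pass removes slow drift and centers the output", {
  n <- 1200; tr <- 4
  ## half-cosine drift with a 400-s period lies inside the filter span
  drift <- cos(pi * 12 * (seq_len(n) - 0.5) / n)  # period 2*4800/12 = 800 s
  res <- highpass_dct(drift, cutoff_hz = 0.01, tr_s = tr)
  expect_lt(sum(res^2) / sum(drift^2), 0.01)
  slow <- cos(2 * pi * (seq_len(n) * tr) / 400 + 0.7)
  res2 <- highpass_dct(slow, cutoff_hz = 0.01, tr_s = tr)
  expect_lt(sum(res2^2) / sum(slow^2), 0.01)
  expect_equal(highpass_dct(rep(3, n), 0.01, tr), rep(0, n),
               ignore_attr = TRUE)
  expect_equal(mean(highpass_dct(rnorm(n), 0.01, tr)), 0, tolerance = 1e-12)
  ## white noise loses exactly the projected dimension fraction on average
  set.seed(2)
  K <- attr(highpass_dct(rnorm(n), 0.01, tr), "dct_dim")
  ratios <- replicate(60, {
    x <- rnorm(n)
    sum(highpass_dct(x, 0.01, tr)^2) / sum(x^2)
  })
  expect_equal(mean(ratios), 1 - K / n, tolerance = 0.01)
})

test_that("respiratory phase regressors track the breathing cycle", {
  fs <- 20; dur <- 400
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  resp <- sin(2 * pi * 0.5 * tt)
  tvol <- seq(2, dur - 2, by = 4)
  rr <- respiratory_phase_regressors(resp, fs, tvol, order = 2)
  expect_equal(dim(rr), c(length(tvol), 4L))
  ## peak-interpolation oracle: peaks at t = 0.5 + 2k, phase
  ## 2*pi*(t - 0.5)/2 at the volume times
  phi <- 2 * pi * (tvol - 0.5) / 2
  expect_equal(rr[, "resp_cos1"], cos(phi), tolerance = 0.02)
  expect_equal(rr[, "resp_sin1"], sin(phi), tolerance = 0.02)
  expect_equal(rr[, "resp_cos2"], cos(2 * phi), tolerance = 0.02)
  expect_error(respiratory_phase_regressors(rep(1, 1000), fs, tvol),
               "no peaks")
  expect_error(respiratory_phase_regressors(resp, 5, tvol), ">= 10 Hz")
})

test_that("confound regression leaves residuals orthogonal to confounds", {
  set.seed(3)
  n <- 200
  conf <- cbind(rnorm(n), rnorm(n), seq_len(n) / n)
  y <- conf %*% c(2, -1, 3) + rnorm(n)
  r <- confound_regress(y, conf)
  expect_lt(max(abs(crossprod(conf, r))) /
              (max(abs(conf)) * sqrt(sum(r^2))), 1e-8)
  ## a series equal to a confound vanishes
  expect_lt(max(abs(confound_regress(conf[, 1], conf))), 1e-10)
  ## an orthogonal series is unchanged (up to its projection on the mean)
  z <- rnorm(n)
  z <- z - mean(z)
  z <- residuals(lm(z ~ conf))
  expect_equal(confound_regress(z, conf), unname(z), tolerance = 1e-10)
  ## normal-equations oracle on a random case
  X <- cbind(1, conf)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(confound_regress(y, conf), as.vector(y - X %*% beta),
               tolerance = 1e-10)
})

test_that("z-scoring uses the population convention", {
  expect_equal(zscore_ts(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  x <- rnorm(50)
  z <- zscore_ts(x)
  expect_equal(zscore_ts(z), z)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_error(zscore_ts(rep(2, 10)), "constant")
})
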