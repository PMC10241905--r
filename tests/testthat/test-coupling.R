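test_that("ROI extraction averages exactly the in-mask voxels", {
  vol <- array(0, c(3, 3, 2, 4))
  vol[1, 1, 1, ] <- c(1, 2, 3, 4)
  vol[2, 1, 1, ] <- c(3, 4, 5, 6)
  vol[3, 3, 2, ] <- 100
  m1 <- array(FALSE, c(3, 3, 2)); m1[1, 1, 1] <- TRUE
  expect_equal(extract_roi_mean(vol, m1), c(1, 2, 3, 4))
  m3 <- m1; m3[2, 1, 1] <- TRUE; m3[3, 3, 2] <- TRUE
  ## hand mean over the three voxels
  expect_equal(extract_roi_mean(vol, m3),
               (c(1, 2, 3, 4) + c(3, 4, 5, 6) + 100) / 3)
  vol2 <- array(7, c(3, 3, 2, 5))
  expect_equal(extract_roi_mean(vol2, m3), rep(7, 5))
  expect_error(extract_roi_mean(vol, array(FALSE, c(3, 3, 2))), "empty")
})

test_that("cross-correlation identifies constructed lags and symmetry", {
  set.seed(9)
  x <- rnorm(200)
  r <- cross_correlation(x, x, max_lag_s = 20, tr_s = 4)
  expect_equal(unname(r["0"]), 1)
  ## CSF = -BOLD shifted one TR later: r(+4) = -1 exactly
  y <- c(0, -x[1:199])
  r2 <- cross_correlation(x, y, max_lag_s = 20, tr_s = 4)
  expect_equal(unname(r2["4"]), -1)
  expect_true(all(abs(r2[names(r2) != "4"]) < 1))
  ## antisymmetry of arguments: r_xy(l) = r_yx(-l)
  z <- rnorm(200)
  rxy <- cross_correlation(x, z, 12, 4)
  ryx <- cross_correlation(z, x, 12, 4)
  expect_equal(unname(rxy), unname(rev(ryx)), tolerance = 1e-12)
  expect_error(cross_correlation(x[1:9], z[1:9], 20, 4), "twice the maximum")
  expect_error(cross_correlation(rep(1, 50), z[1:50], 8, 4),
               "zero-variance")
})

test_that("coupling permutation test reaches its floor and validates input", {
  cfg <- generator_config(coupling_gain = 3,
                          noise_sd_gm = generator_config()$noise_sd_gm / 10,
                          noise_sd_csf = generator_config()$noise_sd_csf / 10)
  ses <- generate_session(cfg, seed = 1)
  ro <- session_roi_series(ses)
  res <- coupling_perm_test(ro$gm, ro$csf, n_perm = 500, seed = 1)
  expect_s3_class(res, "coupling_result")
  expect_equal(res$p_two_sided, 1 / 501)
  expect_equal(res$peak_lag, 4)
  expect_lt(res$peak_r, -0.8)
  expect_true(all(abs(res$mean_r) <= 1))
  expect_true(all(res$null_lo <= res$null_hi))
  expect_error(coupling_perm_test(ro$gm, ro$csf, n_perm = 99), ">= 100")
  expect_error(coupling_perm_test(rnorm(15), rnorm(15), n_perm = 100),
               "20 TR")
})

test_that("permutation p-values are calibrated under independence", {
  set.seed(10)
  nsim <- 300
  p <- replicate(nsim, {
    b <- rnorm(400); c <- rnorm(400)
    coupling_perm_test(b, c, max_lag_s = 8, tr_s = 4, n_perm = 119,
                       seed = sample.int(1e6, 1))$p_two_sided
  })
  rej <- mean(p <= 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("peak lag recovery matches the generator's coupling delay", {
  rec <- vapply(1:20, function(s) {
    ses <- generate_session(seed = s)
    ro <- session_roi_series(ses)
    r <- cross_correlation(ro$gm, ro$csf, max_lag_s = 20, tr_s = 4)
    as.numeric(names(r)[which.max(abs(r))])
  }, numeric(1))
  expect_gte(sum(rec == generator_config()$csf_delay_s), 19)
})

test_that("the 12-s isolation rule keeps only well-separated bouts", {
  ## adjacent bouts: REM onset sits 0 s from the NREM offset
  h <- toy_hypnogram(list("NREM", 30), list("REM", 10))
  f <- filter_isolated_bouts(h, 12)
  expect_equal(f$bouts$state, "NREM")
  ## a 20-s gap across an eye-open bout rescues the REM bout
  h2 <- hypnogram(data.frame(state = c("NREM", "REM"), onset = c(0, 50),
                             duration = c(30, 8)), 100)
  f2 <- filter_isolated_bouts(h2, 12)
  expect_equal(f2$bouts$state, c("NREM", "REM"))
  ## min_sep 0 keeps everything
  f0 <- filter_isolated_bouts(h, 0)
  expect_equal(nrow(f0$bouts), 2)
  ## exhaustive check: every retained bout onset is >= 12 s past every
  ## other NREM/REM offset that precedes it
  h3 <- generate_hypnogram(seed = 13)
  f3 <- filter_isolated_bouts(h3, 12)
  offs <- h3$bouts$onset + h3$bouts$duration
  sel <- h3$bouts$state %in% c("NREM", "REM")
  for (i in seq_len(nrow(f3$bouts))) {
    gaps <- f3$bouts$onset[i] - offs[sel]
    expect_false(any(gaps >= 0 & gaps < 12))
  }
  expect_gt(nrow(f3$bouts), 0)
})

test_that("bout-locked averages align snippets and drop partial windows", {
  ts <- c(rep(0, 10), 1, 2, 3, rep(0, 10), 1, 2, 3, rep(0, 4))
  bouts <- data.frame(state = "NREM", onset = c(40, 92), duration = 10)
  ## onsets at volumes 11 and 24 (TR 4); window [-8, +8]
  bl <- bout_locked_average(ts, bouts, window_s = c(-8, 8), tr_s = 4)
  expect_equal(bl$n_bouts, 2)
  expect_equal(bl$offsets, c(-8, -4, 0, 4, 8))
  expect_equal(bl$mean, c(0, 0, 1, 2, 3))
  expect_equal(bl$sem, rep(0, 5))  # identical snippets
  ## single bout: SEM is zero by convention
  bl1 <- bout_locked_average(ts, bouts[1, ], window_s = c(-8, 8), tr_s = 4)
  expect_equal(bl1$sem, rep(0, 5))
  expect_equal(bl1$mean, c(0, 0, 1, 2, 3))
  ## hand mean/SEM on three distinct snippets
  ts2 <- c(0, 1, 0, 0, 2, 0, 0, 6, 0)
  b3 <- data.frame(state = "REM", onset = c(4, 16, 28), duration = 4)
  bl3 <- bout_locked_average(ts2, b3, window_s = c(0, 0), tr_s = 4)
  expect_equal(bl3$mean, 3)
  expect_equal(bl3$sem, sd(c(1, 2, 6)) / sqrt(3))
  ## a window that never fits errors out
  expect_error(bout_locked_average(ts[1:3], bouts, window_s = c(-8, 8),
                                   tr_s = 4), "fits")
})

test_that("ROI beta comparisons reproduce hand-computed t statistics", {
  a <- c(1, 2, 3); b <- c(2, 3, 5)
  res <- roi_beta_compare(a, b, paired = TRUE)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_hand)
  expect_equal(res$dof, 2)
  same <- roi_beta_compare(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ## two-sample dof bookkeeping
  res2 <- roi_beta_compare(rnorm(8) + 1, rnorm(6), paired = FALSE)
  expect_equal(res2$dof, 12)
  expect_equal(bonferroni(rep(0.01, 3)), rep(0.03, 3))
  expect_equal(bonferroni(c(0.5, 0.9)), c(1, 1))
})
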