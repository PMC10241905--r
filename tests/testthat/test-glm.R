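test_that("design matrix holds convolved state boxcars and derivatives", {
  tr <- 4; nvol <- 60
  h <- hypnogram(data.frame(state = "NREM", onset = 40, duration = 8),
                 nvol * tr)
  expect_warning(des <- build_design(h, tr, nvol), "REM")
  expect_true(all(c("intercept", "NREM", "NREM_deriv") %in%
                    colnames(des$X)))
  expect_false("REM" %in% colnames(des$X))
  ## discrete-convolution hand oracle at three volumes
  dt <- 0.1
  tf <- seq(0, nvol * tr - dt, by = dt)
  box <- as.numeric(tf >= 40 & tf < 48)
  k <- pigeon_hrf(seq(0, 32, by = dt))
  conv <- numeric(length(tf))
  for (j in seq_along(k)) {
    idx <- seq_along(tf) - j + 1
    ok <- idx >= 1
    conv[ok] <- conv[ok] + box[idx[ok]] * k[j] * dt
  }
  tvol <- (seq_len(nvol) - 0.5) * tr
  oracle <- conv[round(tvol / dt) + 1]
  expect_equal(des$X[, "NREM"][c(11, 12, 14)], oracle[c(11, 12, 14)],
               tolerance = 1e-8)
  expect_equal(des$X[, "NREM_deriv"], c(0, diff(des$X[, "NREM"])))
  ## absent states drop their columns; contrasts on them error out
  fit <- fit_glm(rnorm(nvol), des)
  expect_error(glm_contrast(fit, c(REM = 1, NREM = -1)), "absent")
})

test_that("ordinary least squares recovers exact coefficients", {
  set.seed(1)
  X <- cbind(intercept = 1, a = rnorm(30), b = rnorm(30))
  y <- 2 * X[, "a"] + 3 * X[, "b"]
  f <- fit_glm(y, X)
  expect_equal(unname(f$betas[, 1]), c(0, 2, 3), tolerance = 1e-10)
  expect_equal(f$sigma2[[1]], 0, tolerance = 1e-20)
  expect_equal(f$dof, 27)
  Xbad <- cbind(X, a2 = X[, "a"] * 2)
  expect_error(fit_glm(y, Xbad), "a2")
  expect_error(fit_glm(y[1:3], X[1:3, ]), "more volumes")
})

test_that("contrast t matches the hand formula on a tiny worked example", {
  X <- cbind(int = 1, x = c(0, 1, 2, 3, 4, 5))
  y <- c(1.1, 1.9, 3.2, 3.8, 5.1, 5.9)
  f <- fit_glm(y, X)
  ## hand computation via the normal equations
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / 4
  cvec <- c(0, 1)
  t_hand <- drop(cvec %*% beta) / sqrt(s2 * drop(t(cvec) %*% XtXi %*% cvec))
  ct <- glm_contrast(f, c(x = 1))
  expect_equal(ct$t, t_hand, tolerance = 1e-10)
  expect_equal(ct$dof, 4)
  expect_error(glm_contrast(f, c(int = 0, x = 0)), "all zero")
})

test_that("pure-noise t statistics keep nominal type-I error", {
  set.seed(4)
  n <- 30; nsim <- 10000
  X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * nsim), n, nsim)
  f <- fit_glm(Y, X)
  ct <- glm_contrast(f, c(a = 1, b = -1))
  rate <- mean(abs(ct$t) > qt(0.975, f$dof))
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
  ## t is invariant to rescaling the data
  ct2 <- glm_contrast(fit_glm(Y * 7, X), c(a = 1, b = -1))
  expect_equal(ct2$t, ct$t, tolerance = 1e-10)
  ## betas are invariant to rescaling a confound column
  X2 <- X; X2[, "b"] <- X2[, "b"] * 10
  f2 <- fit_glm(Y[, 1:5], X2)
  expect_equal(f2$betas["a", ], fit_glm(Y[, 1:5], X)$betas["a", ],
               tolerance = 1e-10)
})

test_that("AR(1) prewhitening estimates the autocorrelation it removes", {
  set.seed(5)
  n <- 400
  X <- cbind(intercept = 1, x = rnorm(n))
  e <- as.vector(arima.sim(list(ar = 0.5), n))
  y <- 1 + 2 * X[, "x"] + e
  f <- fit_glm(y, X, prewhiten = TRUE)
  expect_equal(f$rho[1], 0.5, tolerance = 0.15)
  expect_equal(unname(f$betas["x", 1]), 2, tolerance = 0.1)
})

test_that("REM>NREM contrast lights up GM voxels and not background", {
  cfg <- small_config(n_volumes = 500)
  ses <- generate_session(cfg, seed = 21)
  des <- build_design(ses$hypnogram, cfg$tr_s, cfg$n_volumes,
                      hrf_params = cfg$hrf_params)
  vmat <- matrix(ses$volumes, prod(cfg$grid_dim), cfg$n_volumes)
  gm_v <- which(as.vector(ses$masks$gm))[1:5]
  bg_v <- which(!as.vector(ses$masks$gm | ses$masks$ivv_bottom |
                             ses$masks$cr))[1:5]
  f <- fit_glm(t(vmat[c(gm_v, bg_v), ]), des)
  ct <- glm_contrast(f, c(REM = 1, NREM = -1))
  expect_true(all(ct$t[1:5] > 2))
  expect_true(all(abs(ct$t[6:10]) < 3))
})

test_that("fixed-effects combination is inverse-variance weighting", {
  ## equal variances reduce to the simple mean
  fe <- fixed_effects_combine(list(1, 3), list(2, 2))
  expect_equal(fe$beta, 2)
  expect_equal(fe$variance, 1)
  ## single session passes through
  fe1 <- fixed_effects_combine(list(c(a = 1.5)), list(c(a = 0.7)))
  expect_equal(unname(fe1$beta), 1.5)
  expect_equal(unname(fe1$variance), 0.7)
  ## unequal case against the closed form
  b <- c(1, 4); v <- c(0.5, 2)
  fe2 <- fixed_effects_combine(as.list(b), as.list(v))
  expect_equal(fe2$beta, sum(b / v) / sum(1 / v))
  expect_equal(fe2$variance, 1 / sum(1 / v))
  expect_error(fixed_effects_combine(list(1), list(0)), "> 0")
})

test_that("two-bird exhaustive sign-flip test enumerates all four flips", {
  m <- matrix(c(1.2, 0.9, 0.8, 1.1, -0.3, 0.2), nrow = 2)
  expect_warning(g <- group_perm_test(m, n_perm = 100, seed = 1),
                 "exhaustively")
  expect_true(g$exhaustive)
  ## brute-force oracle over the 4 sign patterns
  tstat <- function(v) mean(v) / (sd(v) / sqrt(2))
  for (j in 1:3) {
    stats_all <- apply(expand.grid(c(1, -1), c(1, -1)), 1, function(s) {
      max(apply(m * s, 2, tstat))
    })
    expect_equal(g$p_fwe[j], mean(stats_all >= tstat(m[, j])))
  }
  expect_true(all(g$p_fwe %in% c(0.25, 0.5, 0.75, 1)))
})

test_that("permutation FWE control holds on null maps and finds big effects", {
  set.seed(6)
  nb <- 12; nv <- 40
  any_sig <- replicate(12, {
    maps <- matrix(rnorm(nb * nv), nb, nv)
    g <- group_perm_test(maps, n_perm = 499, seed = sample.int(1e6, 1))
    mean(g$p_fwe < 0.05)
  })
  expect_lte(mean(any_sig), 0.05)
  ## a huge common effect hits the attainable floor
  maps <- matrix(5 + rnorm(16 * nv, sd = 0.1), 16, nv)
  g2 <- group_perm_test(maps, n_perm = 999, seed = 2)
  expect_equal(min(g2$p_fwe), 1 / 1000)
})

test_that("TFCE and cluster modes enhance contiguous suprathreshold signal", {
  dims <- c(6, 6, 3)
  nb <- 8
  base <- array(0, dims)
  base[2:4, 2:4, 1:2] <- 3  # a contiguous block
  set.seed(7)
  maps <- t(replicate(nb, as.vector(base) + rnorm(prod(dims), sd = 0.5)))
  gt <- group_perm_test(maps, n_perm = 99, mode = "tfce", seed = 3,
                        dims = dims)
  expect_true(all(gt$p_fwe[as.vector(base) > 0] < 0.05))
  gc <- group_perm_test(maps, n_perm = 199, mode = "cluster", seed = 3,
                        dims = dims, z_thresh = 2.3)
  expect_true(all(gc$p_fwe[as.vector(base) > 0] < 0.05))
  expect_gt(mean(gc$p_fwe[as.vector(base) == 0]), 0.5)
  ## TFCE preserves the maximum's location and is monotone in the stat
  stat <- array(0, dims); stat[3, 3, 2] <- 2; stat[3, 4, 2] <- 1
  tf <- tfce_transform(stat)
  expect_equal(which.max(tf), which.max(stat))
  expect_true(all(tf >= 0))
})
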