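#' Build a first-level state design matrix
#'
#' One regressor per sleep/wake state present in the hypnogram: the
#' state's occupancy boxcar on a fine time grid convolved with the
#' hemodynamic response and sampled at the volume acquisition times,
#' plus its temporal derivative (first difference). Confound columns are
#' appended unconvolved, after an intercept. States with no bouts are
#' dropped with a warning.
#'
#' @param hyp A [hypnogram()] (already re-referenced to the trimmed run).
#' @param tr_s Repetition time, seconds.
#' @param n_volumes Number of volumes.
#' @param hrf_params HRF parameters for [pigeon_hrf()].
#' @param confounds Optional per-volume confound matrix.
#' @param dt Fine grid step for the convolution, seconds.
#' @return Object of class `"design_matrix"`: list with `X` (matrix),
#'   `task_cols`, `confound_cols`, `tr_s`.
#' @export
build_design <- function(hyp, tr_s, n_volumes,
                         hrf_params = generator_config()$hrf_params,
                         confounds = NULL, dt = 0.1) {
  if (nrow(hyp$bouts) &&
      max(hyp$bouts$onset + hyp$bouts$duration) > n_volumes * tr_s + 1e-9) {
    stopf("bouts extend past the session")
  }
  tfine <- seq(0, n_volumes * tr_s - dt, by = dt)
  tvol <- (seq_len(n_volumes) - 0.5) * tr_s
  idx <- pmin(round(tvol / dt) + 1, length(tfine))
  cols <- list(intercept = rep(1, n_volumes))
  task <- character(0)
  for (s in PF_STATES) {
    if (!any(hyp$bouts$state == s)) {
      if (s %in% c("NREM", "REM")) {
        warning(sprintf("state %s has no bouts; column dropped", s),
                call. = FALSE)
      }
      next
    }
    box <- as.numeric(state_at(hyp, tfine) == s)
    conv <- hrf_convolve(box, dt, hrf_params)[idx]
    dcol <- c(0, diff(conv))
    cols[[s]] <- conv
    cols[[paste0(s, "_deriv")]] <- dcol
    task <- c(task, s, paste0(s, "_deriv"))
  }
  X <- do.call(cbind, cols)
  confound_cols <- character(0)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- paste0("confound_", seq_len(ncol(confounds)))
    }
    X <- cbind(X, confounds)
    confound_cols <- colnames(confounds)
  }
  drop0 <- apply(X, 2, function(v) all(v == 0))
  if (any(drop0)) X <- X[, !drop0, drop = FALSE]
  structure(list(X = X, task_cols = intersect(task, colnames(X)),
                 confound_cols = intersect(confound_cols, colnames(X)),
                 tr_s = tr_s),
            class = "design_matrix")
}

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares of every data column on the design, with
#' optional one-iteration AR(1) prewhitening: the lag-1 autocorrelation is
#' estimated per voxel from the OLS residuals, both sides are filtered
#' with `(1, -rho)`, and the model is refit.
#'
#' @param Y Numeric vector or time-by-voxel matrix.
#' @param design A [build_design()] result or a plain design matrix.
#' @param prewhiten Logical; apply AR(1) prewhitening.
#' @return Object of class `"glm_fit"`: `betas` (p x V), `sigma2`, `dof`,
#'   `xtx_inv` (or per-voxel list when prewhitened), column names, `rho`.
#' @export
fit_glm <- function(Y, design, prewhiten = FALSE) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stopf("Y and design have different lengths")
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stopf("design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  if (n <= p) stopf("need more volumes than design columns")
  fit_ols <- function(X, Y) {
    qx <- qr(X)
    betas <- qr.coef(qx, Y)
    res <- Y - X %*% betas
    dof <- n - ncol(X)
    sigma2 <- colSums(res^2) / dof
    list(betas = betas, res = res, dof = dof, sigma2 = sigma2,
         xtx_inv = chol2inv(qr.R(qx)))
  }
  f <- fit_ols(X, Y)
  rho <- NULL
  if (prewhiten) {
    rho <- vapply(seq_len(ncol(Y)), function(v) {
      r <- f$res[, v]
      sum(r[-1] * r[-n]) / sum(r^2)
    }, numeric(1))
    betas <- matrix(NA_real_, p, ncol(Y), dimnames = list(colnames(X), NULL))
    sigma2 <- numeric(ncol(Y))
    xtx_inv <- vector("list", ncol(Y))
    for (v in seq_len(ncol(Y))) {
      w <- function(z) z[-1, , drop = FALSE] - rho[v] * z[-n, , drop = FALSE]
      Xw <- w(X); Yw <- w(Y[, v, drop = FALSE])
      qx <- qr(Xw)
      b <- qr.coef(qx, Yw)
      r <- Yw - Xw %*% b
      betas[, v] <- b
      sigma2[v] <- sum(r^2) / (nrow(Xw) - p)
      xtx_inv[[v]] <- chol2inv(qr.R(qx))
    }
    return(structure(list(betas = betas, sigma2 = sigma2,
                          dof = nrow(X) - 1 - p, xtx_inv = xtx_inv,
                          columns = colnames(X), rho = rho),
                     class = "glm_fit"))
  }
  structure(list(betas = f$betas, sigma2 = f$sigma2, dof = f$dof,
                 xtx_inv = f$xtx_inv, columns = colnames(X), rho = rho),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("GLM fit: %d regressors, %d voxel(s), dof %d%s\n",
              length(x$columns), length(x$sigma2), x$dof,
              if (is.null(x$rho)) "" else ", AR(1)-prewhitened"))
  invisible(x)
}

#' Contrast of GLM parameter estimates
#'
#' t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c) per voxel, with z obtained by
#' mapping the Student-t tail probability through the normal quantile.
#'
#' @param fit A [fit_glm()] result.
#' @param weights Named numeric vector of contrast weights; unnamed
#'   columns get weight 0. All-zero contrasts and references to columns
#'   absent from the design are errors.
#' @return list(`t`, `z`, `effect`, `se`, `dof`) per voxel.
#' @export
glm_contrast <- function(fit, weights) {
  if (is.null(names(weights))) stopf("contrast weights must be named")
  missing_cols <- setdiff(names(weights)[weights != 0], fit$columns)
  if (length(missing_cols)) {
    stopf("contrast references columns absent from the design: %s",
          paste(missing_cols, collapse = ", "))
  }
  cvec <- stats::setNames(rep(0, length(fit$columns)), fit$columns)
  cvec[names(weights)] <- weights
  if (all(cvec == 0)) stopf("contrast weights are all zero")
  eff <- drop(crossprod(cvec, fit$betas))
  if (is.list(fit$xtx_inv)) {
    qf <- vapply(fit$xtx_inv, function(M) {
      drop(crossprod(cvec, M %*% cvec))
    }, numeric(1))
  } else {
    qf <- drop(crossprod(cvec, fit$xtx_inv %*% cvec))
  }
  se <- sqrt(fit$sigma2 * qf)
  tval <- eff / se
  z <- t_to_z(tval, fit$dof)
  list(t = tval, z = z, effect = eff, se = se, dof = fit$dof)
}

## Tail-stable Student-t to standard-normal map, preserving sign.
t_to_z <- function(tval, dof) {
  lp <- stats::pt(abs(tval), dof, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  sign(tval) * z
}

#' Fixed-effects combination across sessions
#'
#' Inverse-variance-weighted average of per-session parameter estimates;
#' the combined variance is `1 / sum(1/var_i)`. Used to average the two
#' sessions of each bird before group inference.
#'
#' @param betas List (or matrix) of per-session estimates.
#' @param variances List (or matrix) of per-session variances, same shape.
#' @return list(beta, variance).
#' @export
fixed_effects_combine <- function(betas, variances) {
  B <- do.call(rbind, lapply(betas, rbind))
  V <- do.call(rbind, lapply(variances, rbind))
  if (!all(dim(B) == dim(V))) stopf("betas and variances differ in shape")
  if (any(V <= 0)) stopf("variances must be > 0")
  W <- 1 / V
  list(beta = colSums(B * W) / colSums(W), variance = 1 / colSums(W))
}

## 6-connectivity connected components of a logical 3D array.
label_clusters <- function(mask3d) {
  d <- dim(mask3d)
  lab <- array(0L, d)
  cur <- 0L
  idx_all <- which(mask3d)
  nbr_off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      a <- arrayInd(v, d)
      for (k in 1:6) {
        p <- a + nbr_off[k, ]
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (mask3d[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

#' Threshold-free cluster enhancement
#'
#' Standard TFCE integral with volumetric defaults H = 2, E = 0.5,
#' 6-neighbor connectivity and step `dh = max(stat)/100`: each voxel
#' accumulates `h^H * extent(h)^E * dh` over thresholds `h` below its
#' value, where `extent(h)` is the size of its cluster at threshold `h`.
#' Only the positive side is enhanced.
#'
#' @param stat3d 3D statistic array.
#' @param H,E TFCE height and extent exponents.
#' @param n_steps Number of integration steps.
#' @return Enhanced 3D array.
#' @export
tfce_transform <- function(stat3d, H = 2, E = 0.5, n_steps = 100) {
  mx <- max(stat3d)
  out <- array(0, dim(stat3d))
  if (mx <= 0) return(out)
  dh <- mx / n_steps
  for (h in seq(dh, mx, by = dh)) {
    lab <- label_clusters(stat3d >= h)
    if (!any(lab > 0)) next
    sizes <- tabulate(lab)
    inc <- numeric(length(sizes) + 1)
    inc[-1] <- sizes^E * h^H * dh
    out <- out + array(inc[lab + 1L], dim(stat3d))
  }
  out
}

#' Sign-flip permutation group test with FWE correction
#'
#' One-sample group inference on per-bird contrast maps by sign-flipping
#' permutations of the one-sample t statistic, with family-wise error
#' control through the permutation distribution of the maximum statistic.
#' Modes: `"maxstat"` (max voxel t), `"tfce"` (maps are TFCE-enhanced
#' before taking maxima), `"cluster"` (clusters formed at `z > z_thresh`,
#' max cluster extent). The statistic is signed (one-sided, positive
#' effects); test `-maps` for the negative direction. When `n_perm` is at
#' least the number of distinct sign patterns (`2^n_birds`), the test
#' warns and enumerates them exhaustively.
#'
#' @param maps n_birds x n_voxels matrix of contrast estimates.
#' @param n_perm Number of permutations.
#' @param mode One of `"maxstat"`, `"tfce"`, `"cluster"`.
#' @param seed Integer seed for the random flips.
#' @param dims 3D grid dimensions (required for tfce/cluster modes).
#' @param z_thresh Cluster-forming z threshold (cluster mode).
#' @return list(`p_fwe` per voxel, `t_obs`, `stat_obs`, `null_max`,
#'   `mode`, `exhaustive`).
#' @export
group_perm_test <- function(maps, n_perm = 5000,
                            mode = c("maxstat", "tfce", "cluster"),
                            seed = NULL, dims = NULL, z_thresh = 2.3) {
  mode <- match.arg(mode)
  maps <- as.matrix(maps)
  nb <- nrow(maps)
  if (nb < 2) stopf("need at least 2 maps")
  if (mode %in% c("tfce", "cluster")) {
    if (is.null(dims)) stopf("dims required for %s mode", mode)
    if (prod(dims) != ncol(maps)) stopf("dims do not match map size")
  }
  tstat <- function(M) {
    n <- nrow(M)
    mu <- colMeans(M)
    v <- (colSums(M^2) - n * mu^2) / (n - 1)
    se <- sqrt(v / n)
    ifelse(se <= 0, 0, mu / se)
  }
  enhance <- function(tv) {
    switch(mode,
           maxstat = tv,
           tfce = as.vector(tfce_transform(array(tv, dims))),
           cluster = {
             z <- t_to_z(tv, nb - 1)
             lab <- label_clusters(array(z > z_thresh, dims))
             sizes <- tabulate(lab)
             as.vector(array(c(0, sizes)[lab + 1L], dims))
           })
  }
  t_obs <- tstat(maps)
  stat_obs <- enhance(t_obs)
  exhaustive <- 2^nb <= n_perm
  if (exhaustive) {
    warning(sprintf(
      "n_perm >= 2^%d distinct sign flips; enumerating exhaustively", nb),
      call. = FALSE)
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), nb)))
  } else {
    flips <- local_seed(seed, {
      matrix(sample(c(1, -1), nb * n_perm, replace = TRUE), n_perm, nb)
    })
  }
  null_max <- apply(flips, 1, function(s) max(enhance(tstat(maps * s))))
  p_fwe <- if (exhaustive) {
    vapply(stat_obs, function(v) mean(null_max >= v), numeric(1))
  } else {
    vapply(stat_obs, function(v) {
      (1 + sum(null_max >= v)) / (n_perm + 1)
    }, numeric(1))
  }
  list(p_fwe = p_fwe, t_obs = t_obs, stat_obs = stat_obs,
       null_max = null_max, mode = mode, exhaustive = exhaustive)
}
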