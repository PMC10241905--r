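#' Mean time series over a mask
#'
#' @param volumes 4D array (x,y,z,t).
#' @param mask Logical 3D array.
#' @return Per-volume mean over in-mask voxels.
#' @export
extract_roi_mean <- function(volumes, mask) {
  d <- dim(volumes)
  if (!all(dim(mask) == d[1:3])) stopf("mask does not match volume grid")
  if (!any(mask)) stopf("empty mask")
  vmat <- matrix(volumes, prod(d[1:3]), d[4])
  colMeans(vmat[as.vector(mask), , drop = FALSE])
}

#' BOLD-CSF cross-correlation over lags
#'
#' Pearson correlation of `bold(t)` with `csf(t + lag)` over the
#' overlapping window, for lags on the grid `-max_lag_s .. +max_lag_s` in
#' TR steps. A positive lag means the CSF series is taken later in time
#' than BOLD, so the paper's "+4 s" peak corresponds to CSF following
#' BOLD by 4 s.
#'
#' @param bold,csf Equal-length numeric series.
#' @param max_lag_s Maximum lag, seconds.
#' @param tr_s Repetition time, seconds.
#' @return Named numeric vector of correlations; names are lags in
#'   seconds.
#' @export
cross_correlation <- function(bold, csf, max_lag_s = 20, tr_s = 4) {
  n <- length(bold)
  if (length(csf) != n) stopf("series lengths differ")
  kmax <- round(max_lag_s / tr_s)
  if (n < 2 * kmax) stopf("series shorter than twice the maximum lag")
  r <- vapply(-kmax:kmax, function(k) {
    if (k >= 0) {
      a <- bold[seq_len(n - k)]
      b <- csf[seq_len(n - k) + k]
    } else {
      a <- bold[seq_len(n + k) - k]
      b <- csf[seq_len(n + k)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stopf("zero-variance overlap at lag %d", k)
    }
    stats::cor(a, b)
  }, numeric(1))
  names(r) <- (-kmax:kmax) * tr_s
  r
}

## Mean lag curve across one or more sessions.
mean_lag_curve <- function(bold, csf, max_lag_s, tr_s) {
  if (!is.list(bold)) {
    bold <- list(bold); csf <- list(csf)
  }
  curves <- mapply(cross_correlation, bold, csf,
                   MoreArgs = list(max_lag_s = max_lag_s, tr_s = tr_s))
  rowMeans(as.matrix(curves))
}

#' Permutation test for BOLD-CSF coupling
#'
#' Computes the session-averaged cross-correlation curve, takes the lag
#' of extreme absolute mean correlation as the observed statistic, and
#' builds the null by circularly shifting each session's CSF series by a
#' uniform random offset of at least 10 TR per permutation (circular
#' shifts preserve autocorrelation, which naive sample shuffling would
#' destroy). The two-sided p-value is `(1 + k) / (n_perm + 1)` where `k`
#' counts null curve extrema at least as large in absolute value; the
#' null band is the pointwise 2.5/97.5 percentile of the null mean
#' curves.
#'
#' @param bold,csf Numeric series, or lists of per-session series.
#' @param max_lag_s Maximum lag, seconds.
#' @param tr_s Repetition time, seconds.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return Object of class `"coupling_result"`: `lags` (s), `mean_r`,
#'   `null_mean`, `null_lo`, `null_hi`, `peak_lag`, `peak_r`,
#'   `p_two_sided`, `n_perm`, `n_sessions`.
#' @export
coupling_perm_test <- function(bold, csf, max_lag_s = 20, tr_s = 4,
                               n_perm = 5000, seed = NULL) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  if (!is.list(bold)) { bold <- list(bold); csf <- list(csf) }
  if (length(bold) != length(csf)) stopf("session counts differ")
  lens <- vapply(bold, length, integer(1))
  if (any(lens < 20)) stopf("series shorter than 20 TR")
  obs <- mean_lag_curve(bold, csf, max_lag_s, tr_s)
  lags <- as.numeric(names(obs))
  ipk <- which.max(abs(obs))
  obs_stat <- abs(obs[ipk])
  null_curves <- local_seed(seed, {
    ## per-session random offsets, >= 10 TR away from the true alignment;
    ## drawn without replacement while the offset pool lasts, so the
    ## permutation distribution is not thinned by duplicates
    offsets <- lapply(csf, function(x) {
      pool <- 10:(length(x) - 10)
      sample(pool, n_perm, replace = n_perm > length(pool))
    })
    vapply(seq_len(n_perm), function(j) {
      csf_sh <- mapply(function(x, off) {
        n <- length(x)
        x[((seq_len(n) - 1 + off[j]) %% n) + 1]
      }, csf, offsets, SIMPLIFY = FALSE)
      mean_lag_curve(bold, csf_sh, max_lag_s, tr_s)
    }, numeric(length(obs)))
  })
  null_max <- apply(abs(null_curves), 2, max)
  p <- (1 + sum(null_max >= obs_stat)) / (n_perm + 1)
  structure(list(lags = lags, mean_r = unname(obs),
                 null_mean = rowMeans(null_curves),
                 null_lo = apply(null_curves, 1, stats::quantile,
                                 probs = 0.025),
                 null_hi = apply(null_curves, 1, stats::quantile,
                                 probs = 0.975),
                 peak_lag = lags[ipk], peak_r = unname(obs[ipk]),
                 p_two_sided = p, n_perm = n_perm,
                 n_sessions = length(bold)),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(paste0("BOLD-CSF coupling: peak r = %.3f at %+g s lag ",
                     "(n = %d session(s), %d permutations, p = %.2g)\n"),
              x$peak_r, x$peak_lag, x$n_sessions, x$n_perm, x$p_two_sided))
  invisible(x)
}

#' Select bouts isolated from preceding state offsets
#'
#' Keeps a NREM/REM bout only when no NREM/REM bout offset falls within
#' `min_sep_s` seconds before (or exactly at) its onset, so bout-locked
#' averages are not contaminated by the response to the preceding bout.
#'
#' @param hyp A [hypnogram()].
#' @param min_sep_s Minimum separation, seconds (12 by default).
#' @param states States whose bouts are filtered and whose offsets count.
#' @return A [hypnogram()] containing the retained bouts only.
#' @export
filter_isolated_bouts <- function(hyp, min_sep_s = 12,
                                  states = c("NREM", "REM")) {
  b <- hyp$bouts
  sel <- b$state %in% states
  offs <- b$onset[sel] + b$duration[sel]
  keep <- vapply(seq_len(nrow(b)), function(i) {
    if (!sel[i]) return(FALSE)
    gap <- b$onset[i] - offs  # own offset gives a negative gap: ignored
    !any(gap >= 0 & gap < min_sep_s)
  }, logical(1))
  hypnogram(b[keep, , drop = FALSE], hyp$session_length)
}

#' Bout-onset-locked average time course
#'
#' Extracts a snippet of the series around each bout onset (aligned to
#' the nearest volume), drops snippets that do not fit entirely inside
#' the series, and returns the mean and SEM across bouts per offset.
#'
#' @param ts Per-volume numeric series.
#' @param bouts A [hypnogram()] or data.frame of bouts to lock on.
#' @param window_s `c(before, after)` window relative to onset, seconds.
#' @param tr_s Repetition time, seconds.
#' @return Object of class `"bout_locked_average"`: `offsets` (s),
#'   `mean`, `sem`, `n_bouts`.
#' @export
bout_locked_average <- function(ts, bouts, window_s = c(-8, 20), tr_s = 4) {
  b <- if (inherits(bouts, "hypnogram")) bouts$bouts else bouts
  k0 <- round(window_s[1] / tr_s)
  k1 <- round(window_s[2] / tr_s)
  offs <- k0:k1
  snips <- list()
  for (i in seq_len(nrow(b))) {
    v0 <- floor(b$onset[i] / tr_s) + 1  # volume containing the onset
    idx <- v0 + offs
    if (idx[1] < 1 || idx[length(idx)] > length(ts)) next
    snips[[length(snips) + 1]] <- ts[idx]
  }
  if (!length(snips)) stopf("no bout window fits inside the series")
  M <- do.call(rbind, snips)
  nb <- nrow(M)
  structure(list(offsets = offs * tr_s, mean = colMeans(M),
                 sem = if (nb > 1) apply(M, 2, stats::sd) / sqrt(nb)
                       else rep(0, ncol(M)),
                 n_bouts = nb),
            class = "bout_locked_average")
}

#' @export
print.bout_locked_average <- function(x, ...) {
  cat(sprintf("Bout-locked average over %d bouts, offsets %g..%g s\n",
              x$n_bouts, min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Compare ROI parameter estimates between conditions
#'
#' Paired or two-sample Student t-test on per-bird parameter estimates
#' (dof = n - 1 paired, n1 + n2 - 2 two-sample).
#'
#' @param beta_a,beta_b Per-bird estimates for the two conditions.
#' @param paired Logical.
#' @return list(`t`, `dof`, `p`, `mean_diff`).
#' @export
roi_beta_compare <- function(beta_a, beta_b, paired = TRUE) {
  if (paired && length(beta_a) != length(beta_b)) {
    stopf("paired comparison needs equal-length vectors")
  }
  if (paired && stats::sd(beta_a - beta_b) == 0) {
    ## degenerate paired case: identical vectors carry no evidence
    d <- mean(beta_a - beta_b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                dof = length(beta_a) - 1,
                p = if (d == 0) 1 else 0, mean_diff = d))
  }
  ht <- stats::t.test(beta_a, beta_b, paired = paired, var.equal = TRUE)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p = ht$p.value,
       mean_diff = if (paired) mean(beta_a - beta_b)
                   else mean(beta_a) - mean(beta_b))
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size, capped at 1.
#'
#' @param pvals Numeric p-values.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals) {
  stats::p.adjust(pvals, method = "bonferroni")
}
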