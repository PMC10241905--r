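#' Construct a hypnogram
#'
#' A hypnogram is an ordered, non-overlapping sequence of state bouts
#' (NREM, REM, and the three eye-open variants) on a session timeline.
#' Bout intervals are half-open `[onset, onset + duration)` in seconds.
#'
#' @param bouts data.frame with columns `state` (character), `onset` and
#'   `duration` (seconds).
#' @param session_length Session length in seconds.
#' @return An object of class `"hypnogram"`: a list with elements `bouts`
#'   (data.frame) and `session_length`.
#' @export
hypnogram <- function(bouts, session_length) {
  stopifnot(is.data.frame(bouts))
  need <- c("state", "onset", "duration")
  if (!all(need %in% names(bouts))) {
    stopf("hypnogram bouts need columns: %s", paste(need, collapse = ", "))
  }
  bouts <- bouts[order(bouts$onset), need, drop = FALSE]
  rownames(bouts) <- NULL
  if (nrow(bouts)) {
    if (any(bouts$duration <= 0)) stopf("all bout durations must be > 0")
    if (any(bouts$onset < 0)) stopf("bout onsets must be >= 0")
    ends <- bouts$onset + bouts$duration
    if (any(ends > session_length + 1e-9)) {
      stopf("bouts extend past session_length")
    }
    if (nrow(bouts) > 1 &&
        any(bouts$onset[-1] < ends[-nrow(bouts)] - 1e-9)) {
      stopf("bouts overlap")
    }
    bad <- setdiff(unique(bouts$state), c(PF_STATES, PF_UNSCORED))
    if (length(bad)) stopf("unknown states: %s", paste(bad, collapse = ", "))
  }
  structure(list(bouts = bouts, session_length = session_length),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("Hypnogram: %d bouts over %.1f s\n",
              nrow(x$bouts), x$session_length))
  tab <- table(factor(x$bouts$state, levels = PF_STATES))
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.hypnogram <- function(x, ...) x$bouts

#' Generate a ground-truth hypnogram from the semi-Markov bout process
#'
#' States alternate by a semi-Markov chain in which REM is entered only
#' from NREM; dwell times are gamma-distributed with per-state mean and
#' shape, redrawn until at least 2 s (shorter bouts are not scoreable at
#' 1-s epochs with a 2-s transition discard). Defaults are calibrated so
#' an 80-minute session averages about 85 NREM and 72 REM bouts.
#'
#' @param config A [generator_config()] list.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(config = generator_config(), seed = NULL) {
  config <- validate_generator_config(config)
  L <- config$tr_s * config$n_volumes
  probs <- config$state_probs
  for (s in names(probs)) {
    p <- probs[[s]]
    if (any(p < 0) || sum(p) <= 0) {
      stopf("transition weights from %s are not normalizable", s)
    }
    probs[[s]] <- p / sum(p)
  }
  local_seed(seed, {
    state <- "NREM"
    onsets <- numeric(0); durs <- numeric(0); states <- character(0)
    t <- 0
    while (t < L) {
      dw <- config$state_dwell[[state]]
      repeat {
        d <- stats::rgamma(1, shape = dw[["shape"]],
                           scale = dw[["mean"]] / dw[["shape"]])
        if (d >= 2) break
      }
      d <- min(d, L - t)
      states <- c(states, state); onsets <- c(onsets, t); durs <- c(durs, d)
      t <- t + d
      p <- probs[[state]]
      state <- sample(names(p), 1, prob = p)
    }
    hypnogram(data.frame(state = states, onset = onsets, duration = durs,
                         stringsAsFactors = FALSE), session_length = L)
  })
}

#' Per-state bout counts and durations
#'
#' @param hyp A [hypnogram()].
#' @param states States to tabulate (default the five scoreable states).
#' @return data.frame with one row per state: `state`, `count`,
#'   `mean_duration`, `median_duration`, `total_duration` (seconds).
#' @export
bout_statistics <- function(hyp, states = PF_STATES) {
  stopifnot(inherits(hyp, "hypnogram"))
  b <- hyp$bouts
  out <- data.frame(state = states, count = 0L, mean_duration = NA_real_,
                    median_duration = NA_real_, total_duration = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(states)) {
    d <- b$duration[b$state == states[i]]
    out$count[i] <- length(d)
    if (length(d)) {
      out$mean_duration[i] <- mean(d)
      out$median_duration[i] <- stats::median(d)
      out$total_duration[i] <- sum(d)
    }
  }
  out
}

## Piecewise-constant lookup of state at arbitrary times. Times outside
## any bout (possible after discards) return `fill`.
state_at <- function(hyp, times, fill = PF_UNSCORED) {
  b <- hyp$bouts
  out <- rep(fill, length(times))
  if (!nrow(b)) return(out)
  idx <- findInterval(times, b$onset)
  ok <- idx >= 1
  inb <- ok & times < (b$onset[pmax(idx, 1)] + b$duration[pmax(idx, 1)])
  out[inb] <- b$state[idx[inb]]
  out
}

#' Shift a hypnogram's time origin
#'
#' Re-references bout onsets after discarding an initial span of the
#' session (e.g. the first 5 trimmed volumes). Bouts ending before the
#' new origin are dropped; bouts straddling it or the new end are clipped.
#'
#' @param hyp A [hypnogram()].
#' @param by_s Seconds to subtract from all onsets.
#' @param new_length New session length in seconds (default: old minus `by_s`).
#' @return A [hypnogram()].
#' @export
shift_hypnogram <- function(hyp, by_s, new_length = hyp$session_length - by_s) {
  b <- hyp$bouts
  b$onset <- b$onset - by_s
  end <- b$onset + b$duration
  b <- b[end > 0 & b$onset < new_length, , drop = FALSE]
  if (nrow(b)) {
    newon <- pmax(b$onset, 0)
    newend <- pmin(b$onset + b$duration, new_length)
    b$onset <- newon
    b$duration <- newend - newon
    b <- b[b$duration > 0, , drop = FALSE]
  }
  hypnogram(b, new_length)
}
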