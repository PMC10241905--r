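#' Behavioral sleep-scoring rules
#'
#' Thresholds for converting actimetry traces into per-epoch state labels:
#' 1-s epochs, an eye counts as open when its aperture exceeds two thirds
#' and as completely closed below one third, motion channels are compared
#' against `motion_threshold` after removing the breathing oscillation
#' from the bill channel, and `transition_discard_s` seconds are discarded
#' at every state change when epochs are merged into bouts. A state is
#' attributed to an epoch only when its defining conditions hold for the
#' full epoch (`occupancy = 1`); anything ambiguous is left UNSCORED.
#'
#' @param epoch_s Epoch length, seconds.
#' @param open_fraction Aperture above which an eye is open (default 2/3).
#' @param closed_fraction Aperture below which an eye is closed (default 1/3).
#' @param motion_threshold Motion-channel threshold (trace units).
#' @param transition_discard_s Seconds discarded at each state change.
#' @param occupancy Fraction of the epoch a state must fill (default 1).
#' @param resp_rate_hz Breathing rate removed from the bill channel
#'   (band-stop at this rate +/- 0.2 Hz).
#' @return A list of class `"scoring_rules"`.
#' @export
scoring_rules <- function(epoch_s = 1, open_fraction = 2 / 3,
                          closed_fraction = 1 / 3, motion_threshold = 1,
                          transition_discard_s = 2, occupancy = 1,
                          resp_rate_hz = 0.5) {
  if (!(closed_fraction > 0 && closed_fraction < open_fraction &&
        open_fraction < 1)) {
    stopf("need 0 < closed_fraction < open_fraction < 1")
  }
  if (epoch_s <= 0) stopf("epoch_s must be > 0")
  structure(list(epoch_s = epoch_s, open_fraction = open_fraction,
                 closed_fraction = closed_fraction,
                 motion_threshold = motion_threshold,
                 transition_discard_s = transition_discard_s,
                 occupancy = occupancy, resp_rate_hz = resp_rate_hz),
            class = "scoring_rules")
}

## Remove the breathing oscillation (and the DC level) from the bill
## channel: FFT band-stop at resp_rate_hz +/- 0.2 Hz. Returns the
## magnitude of the residual motion.
remove_breathing <- function(x, fs, resp_rate_hz, half_width_hz = 0.2) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)  # two-sided frequency axis
  X[abs(f - resp_rate_hz) <= half_width_hz] <- 0
  abs(Re(stats::fft(X, inverse = TRUE)) / n)
}

#' Score actimetry into per-epoch state labels
#'
#' Applies the behavioral definitions frame-wise and attributes a state to
#' an epoch only when its conditions hold for the whole epoch: NREM =
#' bilateral eye closure with all motion channels at the noise floor;
#' REM = bilateral eye closure with iris and/or bill motion above
#' threshold; eye-open states = the respective aperture above two thirds
#' with the other eye completely closed (or both above two thirds).
#' Epochs matching zero definitions are UNSCORED.
#'
#' @param actimetry An `"actimetry"` object (see [generate_actimetry()])
#'   or a list with `fps` and `channels`.
#' @param rules A [scoring_rules()].
#' @return Character vector of labels, one per whole epoch.
#' @export
score_epochs <- function(actimetry, rules = scoring_rules()) {
  fps <- actimetry$fps
  ch <- actimetry$channels
  fpe <- fps * rules$epoch_s
  if (fpe < 1) stopf("fps * epoch_s is below one frame per epoch")
  fpe <- round(fpe)
  n_ep <- floor(nrow(ch) / fpe)
  if (n_ep < 1) stopf("traces cover less than one epoch")
  bill_clean <- remove_breathing(ch$bill_motion, fps, rules$resp_rate_hz)
  epmat <- function(x) matrix(x[seq_len(n_ep * fpe)], nrow = fpe)
  epmax <- function(x) apply(epmat(x), 2, max)
  epmin <- function(x) apply(epmat(x), 2, min)
  thr <- rules$motion_threshold
  closed_l <- epmax(ch$left_eye_aperture) < rules$closed_fraction
  closed_r <- epmax(ch$right_eye_aperture) < rules$closed_fraction
  open_l <- epmin(ch$left_eye_aperture) > rules$open_fraction
  open_r <- epmin(ch$right_eye_aperture) > rules$open_fraction
  moving <- epmax(ch$left_iris_motion) > thr |
    epmax(ch$right_iris_motion) > thr | epmax(bill_clean) > thr
  cand <- cbind(NREM = closed_l & closed_r & !moving,
                REM = closed_l & closed_r & moving,
                LEFT_OPEN = open_l & closed_r,
                RIGHT_OPEN = open_r & closed_l,
                BOTH_OPEN = open_l & open_r)
  nmatch <- rowSums(cand)
  labels <- rep(PF_UNSCORED, n_ep)
  one <- nmatch == 1
  labels[one] <- colnames(cand)[max.col(cand[one, , drop = FALSE])]
  labels
}

#' Merge epoch labels into bouts, discarding transitions
#'
#' Maximal runs of identical labels become bouts; `transition_discard_s`
#' seconds are removed from both ends of every run (session edges are
#' treated like state changes, since the preceding state is unknown), so
#' runs no longer than twice the discard vanish. UNSCORED runs never
#' produce bouts.
#'
#' @param labels Character labels from [score_epochs()].
#' @param rules A [scoring_rules()].
#' @return A [hypnogram()] spanning `length(labels) * epoch_s` seconds.
#' @export
epochs_to_bouts <- function(labels, rules = scoring_rules()) {
  es <- rules$epoch_s
  d <- rules$transition_discard_s
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  onset <- starts * es + d
  dur <- r$lengths * es - 2 * d
  keep <- r$values != PF_UNSCORED & dur > 0
  hypnogram(data.frame(state = r$values[keep], onset = onset[keep],
                       duration = dur[keep], stringsAsFactors = FALSE),
            session_length = length(labels) * es)
}

#' Fraction of epochs on which scoring recovers the generating hypnogram
#'
#' Compares scored epoch labels with the ground-truth state at each epoch
#' midpoint, excluding epochs within `transition_discard_s` of a true bout
#' boundary and epochs scored UNSCORED (both are discarded by the scoring
#' procedure itself).
#'
#' @param labels Scored labels.
#' @param hyp Ground-truth [hypnogram()].
#' @param rules A [scoring_rules()].
#' @return Agreement fraction in \[0, 1\].
#' @export
label_agreement <- function(labels, hyp, rules = scoring_rules()) {
  es <- rules$epoch_s
  mid <- (seq_along(labels) - 0.5) * es
  truth <- state_at(hyp, mid)
  edges <- c(hyp$bouts$onset, hyp$bouts$onset + hyp$bouts$duration)
  near_edge <- vapply(mid, function(m) {
    any(abs(m - edges) < rules$transition_discard_s)
  }, logical(1))
  use <- !near_edge & labels != PF_UNSCORED & truth != PF_UNSCORED
  if (!any(use)) return(NA_real_)
  mean(labels[use] == truth[use])
}
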