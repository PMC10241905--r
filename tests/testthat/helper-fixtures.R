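## Shared fixtures: everything is built in code at test time.

## Hypnogram from a compact spec: list of c(state, duration).
toy_hypnogram <- function(..., session_length = NULL) {
  specs <- list(...)
  onset <- 0
  rows <- lapply(specs, function(s) {
    r <- data.frame(state = s[[1]], onset = onset,
                    duration = as.numeric(s[[2]]))
    onset <<- onset + as.numeric(s[[2]])
    r
  })
  b <- do.call(rbind, rows)
  hypnogram(b, session_length %||% onset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Small, fast generator configuration for tests that do not probe the
## calibrated defaults.
small_config <- function(...) {
  args <- list(n_volumes = 250, grid_dim = c(8L, 8L, 4L))
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(generator_config, args)
}

## ROI mean series of a generated session, cleaned the way the coupling
## analysis consumes them.
session_roi_series <- function(ses) {
  list(gm = zscore_ts(extract_roi_mean(ses$volumes, ses$masks$gm)),
       csf = zscore_ts(extract_roi_mean(ses$volumes, ses$masks$ivv_bottom)))
}

## Actimetry object built directly from per-epoch channel values
## (constant within each 1-s epoch), at a given fps.
flat_actimetry <- function(n_epochs, fps = 30,
                           left = 0, right = 0,
                           iris_l = 0, iris_r = 0, bill = 0) {
  rep_ep <- function(v) rep(rep(v, length.out = n_epochs), each = fps)
  list(fps = fps,
       channels = data.frame(
         left_eye_aperture = rep_ep(left),
         right_eye_aperture = rep_ep(right),
         left_iris_motion = rep_ep(iris_l),
         right_iris_motion = rep_ep(iris_r),
         bill_motion = rep_ep(bill)))
}
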