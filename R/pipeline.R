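#' Run the full analysis pipeline on a synthetic session group
#'
#' Executes simulate -> score -> preprocess -> GLM -> coupling end to end
#' and writes every stage's outputs under `out_dir` in a BIDS-like layout
#' (`sub-XX/` directories; events/motion/ROI series as TSV, volumes as
#' NIfTI, summary statistics as JSON), plus a provenance record. Each
#' stage consumes the files the previous stage wrote, so any stage can be
#' re-run from disk.
#'
#' @param config Either a [read_run_config()] list or a path to a YAML
#'   config. Recognized blocks: `generator` (overrides for
#'   [generator_config()]), `coupling` (`max_lag_s`, `n_perm`),
#'   `n_sessions`.
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param n_sessions Number of sessions to simulate (default 2).
#' @return Invisibly, a list with the per-session results and the group
#'   [coupling_perm_test()] result.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = tempfile(),
                         n_sessions = 2) {
  if (is.character(config)) config <- read_run_config(config)
  gen_over <- config$generator %||% list()
  gcfg <- do.call(generator_config, gen_over)
  n_sessions <- config$n_sessions %||% n_sessions
  max_lag_s <- (config$coupling %||% list())$max_lag_s %||% 20
  n_perm <- (config$coupling %||% list())$n_perm %||% 1000
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sessions <- vector("list", n_sessions)
  bold <- list(); csf <- list()
  for (i in seq_len(n_sessions)) {
    sdir <- file.path(out_dir, sprintf("sub-%02d", i), "func")
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    ses <- generate_session(gcfg, seed = derive_seed(seed, 100 + i))
    write_events_tsv(ses$hypnogram, file.path(sdir, "events.tsv"))
    write_series_tsv(ses$motion, file.path(sdir, "motion.tsv"))
    write_series_tsv(data.frame(respiration = ses$respiration$trace),
                     file.path(sdir, "respiration.tsv"))
    write_volumes_nii(ses$volumes, file.path(sdir, "func.nii.gz"),
                      ses$voxel_mm, ses$tr_s)

    ## scoring from actimetry, for comparison with the ground truth
    labels <- score_epochs(ses$actimetry,
                           scoring_rules(resp_rate_hz = gcfg$resp_rate_hz))
    scored <- epochs_to_bouts(labels)
    write_events_tsv(scored, file.path(sdir, "events_scored.tsv"))

    ## preprocessing: trim, confounds, ROI extraction, cleaning
    tr <- ses$tr_s
    vol <- trim_volumes(ses$volumes)
    motion <- ses$motion[6:(nrow(ses$motion) - 5), , drop = FALSE]
    fd <- framewise_displacement(motion)
    cen <- censor_frames(fd)
    tvol <- (seq_len(dim(vol)[4]) - 0.5) * tr + 5 * tr
    resp_reg <- respiratory_phase_regressors(
      ses$respiration$trace, ses$respiration$fs, tvol)
    conf <- cbind(motion, resp_reg, cen$spikes)
    write_series_tsv(cbind(fd = fd, conf), file.path(sdir, "confounds.tsv"))
    gm <- extract_roi_mean(vol, ses$masks$gm)
    iv <- extract_roi_mean(vol, ses$masks$ivv_bottom)
    gm <- zscore_ts(confound_regress(highpass_dct(gm, tr_s = tr), conf))
    iv <- zscore_ts(confound_regress(highpass_dct(iv, tr_s = tr), conf))
    write_series_tsv(data.frame(gm = gm, csf = iv),
                     file.path(sdir, "roi_series.tsv"))

    ## first-level state GLM on the ROI series
    hyp_trim <- shift_hypnogram(ses$hypnogram, 5 * tr,
                                new_length = dim(vol)[4] * tr)
    des <- build_design(hyp_trim, tr, dim(vol)[4],
                        hrf_params = gcfg$hrf_params, confounds = conf)
    fit <- fit_glm(cbind(gm = gm, csf = iv), des)
    betas <- as.data.frame(t(fit$betas))
    betas$roi <- c("gm", "csf")
    write_series_tsv(betas, file.path(sdir, "glm_betas.tsv"))

    sessions[[i]] <- list(session = ses, scored = scored, fit = fit,
                          gm = gm, csf = iv)
    bold[[i]] <- gm; csf[[i]] <- iv
  }

  cres <- coupling_perm_test(bold, csf, max_lag_s = max_lag_s,
                             tr_s = gcfg$tr_s, n_perm = n_perm,
                             seed = derive_seed(seed, 999))
  jsonlite::write_json(
    list(peak_lag = cres$peak_lag, peak_r = cres$peak_r,
         p_two_sided = cres$p_two_sided, n_sessions = cres$n_sessions),
    file.path(out_dir, "coupling.json"), auto_unbox = TRUE, digits = NA)
  write_series_tsv(data.frame(lag_s = cres$lags, mean_r = cres$mean_r,
                              null_lo = cres$null_lo,
                              null_hi = cres$null_hi),
                   file.path(out_dir, "coupling_lags.tsv"))
  write_provenance(out_dir, list(generator = gen_over,
                                 n_sessions = n_sessions,
                                 coupling = list(max_lag_s = max_lag_s,
                                                 n_perm = n_perm)), seed)
  invisible(list(sessions = sessions, coupling = cres, out_dir = out_dir))
}
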