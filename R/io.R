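#' Write 4D volumes as NIfTI-1
#'
#' @param volumes 4D array (x,y,z,t).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Isotropic voxel size, mm.
#' @param tr_s Repetition time, seconds (stored in pixdim\[4\]).
#' @return The path, invisibly.
#' @export
write_volumes_nii <- function(volumes, path, voxel_mm = 1, tr_s = 4) {
  img <- RNifti::asNifti(volumes)
  RNifti::pixdim(img) <- c(rep(voxel_mm, 3), tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read NIfTI-1 volumes
#'
#' @param path NIfTI file path.
#' @return list(`volumes` (array), `voxel_mm`, `tr_s`).
#' @export
read_volumes_nii <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(volumes = unclass(as.array(img)), voxel_mm = pd[1],
       tr_s = if (length(pd) >= 4) pd[4] else NA_real_)
}

#' Write a hypnogram as a BIDS-style events.tsv
#'
#' Columns `onset`, `duration`, `trial_type`; seconds, 0-based, half-open
#' intervals.
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(hyp, path) {
  df <- data.frame(onset = hyp$bouts$onset, duration = hyp$bouts$duration,
                   trial_type = hyp$bouts$state)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events.tsv into a hypnogram
#'
#' @param path events.tsv path.
#' @param session_length Session length, seconds; default: last offset.
#' @return A [hypnogram()].
#' @export
read_events_tsv <- function(path, session_length = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("events file %s is missing column(s): %s", path,
          paste(miss, collapse = ", "))
  }
  if (is.null(session_length)) {
    session_length <- max(df$onset + df$duration)
  }
  hypnogram(data.frame(state = df$trial_type, onset = df$onset,
                       duration = df$duration, stringsAsFactors = FALSE),
            session_length)
}

#' Write/read a numeric table as TSV with a header row
#'
#' Used for motion parameters, respiration, actimetry, confounds, ROI
#' series and per-lag curves; `read_series_tsv(write_series_tsv(x))`
#' round-trips losslessly to printed precision (17 significant digits).
#'
#' @param x data.frame or matrix.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_series_tsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read and validate a run configuration (YAML)
#'
#' Top-level keys are restricted to the known schema blocks; unknown keys
#' are rejected so typos fail loudly.
#'
#' @param path YAML config path.
#' @return Named list of config blocks.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "generator", "scoring", "preprocess",
             "glm", "coupling", "eeg")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Write a provenance record for a pipeline run
#'
#' Records the package version, seed, a hash of the effective
#' configuration and a timestamp as JSON next to the run outputs.
#'
#' @param out_dir Output directory.
#' @param config Effective configuration list.
#' @param seed Seed used for the run.
#' @return Path of the record, invisibly.
#' @export
write_provenance <- function(out_dir, config, seed) {
  rec <- list(
    package = "pigeonflow",
    version = as.character(utils::packageVersion("pigeonflow")),
    seed = seed,
    config_hash = fnv1a32(yaml::as.yaml(config)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
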