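# Session round-tripping (CSV/TSV dialect) and pipeline configuration.
#
# A session is written as three text files sharing a stem:
#   <id>_signals.csv  columns fp1_uv, fp2_uv (one row per sample)
#   <id>_events.tsv   columns onset_ms, event_type (standard/target/press),
#                     tone_frequency_hz (empty for presses)
#   <id>_meta.json    subject_id, sample_rate
# Events round-trip exactly (times carry millisecond precision to 3
# decimals); samples round-trip well below the 16-bit amplitude-quantization
# step of clinical EEG storage formats.

#' Write a session recording
#'
#' @param recording A `session_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_session <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, recording$subject_id)
  sig_path <- paste0(stem, "_signals.csv")
  ev_path <- paste0(stem, "_events.tsv")
  meta_path <- paste0(stem, "_meta.json")
  data.table::fwrite(data.table::data.table(fp1_uv = recording$fp1,
                                            fp2_uv = recording$fp2),
                     sig_path)
  ev <- rbind(
    data.frame(onset_ms = recording$stimuli$onset_ms,
               event_type = recording$stimuli$kind,
               tone_frequency_hz = recording$stimuli$tone_frequency_hz),
    data.frame(onset_ms = recording$responses$press_time_ms,
               event_type = "press", tone_frequency_hz = NA_real_))
  ev <- ev[order(ev$onset_ms), ]
  data.table::fwrite(ev, ev_path, sep = "\t")
  jsonlite::write_json(list(subject_id = recording$subject_id,
                            sample_rate = recording$sample_rate),
                       meta_path, auto_unbox = TRUE)
  invisible(c(signals = sig_path, events = ev_path, meta = meta_path))
}

#' Read a session recording written by [write_session()]
#'
#' @param dir Directory containing the files.
#' @param subject_id File stem.
#' @return A `session_recording`.
#' @export
read_session <- function(dir, subject_id) {
  stem <- file.path(dir, subject_id)
  sig_path <- paste0(stem, "_signals.csv")
  ev_path <- paste0(stem, "_events.tsv")
  meta_path <- paste0(stem, "_meta.json")
  for (p in c(sig_path, ev_path, meta_path)) {
    if (!file.exists(p)) stop("missing session file: ", p)
  }
  sig <- data.table::fread(sig_path)
  for (col in c("fp1_uv", "fp2_uv")) {
    if (!col %in% names(sig)) {
      stop("parse error in ", sig_path, ": missing required column '", col, "'")
    }
  }
  ev <- data.table::fread(ev_path)
  for (col in c("onset_ms", "event_type", "tone_frequency_hz")) {
    if (!col %in% names(ev)) {
      stop("parse error in ", ev_path, ": missing required column '", col, "'")
    }
  }
  meta <- jsonlite::read_json(meta_path)
  stim <- ev[ev$event_type %in% c("standard", "target"), ]
  stim <- stim[order(stim$onset_ms), ]
  press <- sort(ev$onset_ms[ev$event_type == "press"])
  structure(list(subject_id = meta$subject_id,
                 sample_rate = meta$sample_rate,
                 fp1 = sig$fp1_uv, fp2 = sig$fp2_uv,
                 stimuli = data.frame(onset_ms = stim$onset_ms,
                                      kind = stim$event_type,
                                      tone_frequency_hz = stim$tone_frequency_hz),
                 responses = data.frame(press_time_ms = press)),
            class = "session_recording")
}

#' Pipeline configuration
#'
#' Bundles every tunable of the simulate-measure-test pipeline. The defaults
#' are the analysis' stated recording and measurement parameters: 250 Hz,
#' 64 targets / 256 standards, `[-200, 800)` ms epochs, 300--600 ms peak
#' window, 9-tap smoothing, `[100, 1000]` ms response window, and the
#' reference group sizes 239/95.
#'
#' @param seed Master seed.
#' @param n_cn,n_mci Cohort sizes.
#' @param n_target,n_standard,isi_range_ms Stimulus-sequence settings.
#' @param calibration Calibration list, see [default_calibration()].
#' @param erp ERP measurement options, see [erp_options()].
#' @param standardize_predictors,alpha Statistics options.
#' @param extreme_error_ratio Subjects with `ER` above this are excluded as
#'   extreme-error performers.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_cn = 239, n_mci = 95,
                            n_target = 64, n_standard = 256,
                            isi_range_ms = c(900, 1100),
                            calibration = default_calibration(),
                            erp = erp_options(),
                            standardize_predictors = TRUE, alpha = 0.05,
                            extreme_error_ratio = 1) {
  structure(list(seed = as.integer(seed), n_cn = n_cn, n_mci = n_mci,
                 n_target = n_target, n_standard = n_standard,
                 isi_range_ms = isi_range_ms, calibration = calibration,
                 erp = erp, standardize_predictors = standardize_predictors,
                 alpha = alpha, extreme_error_ratio = extreme_error_ratio),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_pipeline_config` invisibly returns `path`;
#'   `read_pipeline_config` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  raw <- unclass(config)
  # yaml drops names on atomic vectors; keep the per-group map explicit
  raw$calibration$sex_male_prob <- as.list(raw$calibration$sex_male_prob)
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$calibration$groups <- lapply(raw$calibration$groups, function(g) {
    out <- as.data.frame(g)
    out$lower <- as.numeric(out$lower)
    out$upper <- as.numeric(out$upper)
    out
  })
  raw$calibration$sex_male_prob <- unlist(raw$calibration$sex_male_prob)
  structure(raw, class = "pipeline_config")
}
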