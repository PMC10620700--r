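#' Generate a simulated two-group oddball cohort
#'
#' Draws `n_cn` cognitively-normal and `n_mci` mild-cognitive-impairment
#' subjects. The master seed spawns a triple of per-subject seeds (parameters,
#' stimulus sequence, session synthesis) by sequential draws, so a cohort is
#' bit-reproducible and its first subjects do not change when the cohort is
#' enlarged.
#'
#' @param n_cn,n_mci Group sizes (reference cohort: 239 and 95).
#' @param config Calibration list, see [default_calibration()].
#' @param seed Master integer seed.
#' @param n_target,n_standard,isi_range_ms Stimulus-sequence settings passed to
#'   [generate_stimulus_sequence()].
#' @param keep_sessions Keep the synthesized recordings in the bundle
#'   (set `FALSE` to retain only subject records and seeds; sessions can be
#'   regenerated deterministically from the stored seeds).
#' @return A list of class `cohort_bundle`: `subjects` (data frame of subject
#'   records incl. per-subject seeds), `sessions` (named list of
#'   `session_recording` or `NULL`), `params` (named list of `subject_params`)
#'   and `config_digest`.
#' @export
generate_cohort <- function(n_cn = 239, n_mci = 95,
                            config = default_calibration(), seed = 11L,
                            n_target = 64, n_standard = 256,
                            isi_range_ms = c(900, 1100),
                            keep_sessions = TRUE) {
  stopifnot(n_cn >= 0, n_mci >= 0)
  groups <- c(rep("CN", n_cn), rep("MCI", n_mci))
  n <- length(groups)
  seeds <- derive_subject_seeds(seed, n, per = 3L)
  ids <- sprintf("%s%03d", groups, c(seq_len(n_cn), seq_len(n_mci)))

  subjects <- vector("list", n)
  sessions <- if (keep_sessions) vector("list", n) else NULL
  params_list <- vector("list", n)
  for (i in seq_len(n)) {
    p <- simulate_subject_params(groups[i], config, seed = seeds[i, 1])
    params_list[[i]] <- p
    subjects[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i],
      age_years = p$age_years, sex = p$sex,
      sex_male = as.integer(p$sex == "male"),
      education_years = p$education_years, mmse = p$mmse,
      snsb_attention = p$snsb_attention, snsb_language = p$snsb_language,
      snsb_visuospatial = p$snsb_visuospatial, snsb_memory = p$snsb_memory,
      snsb_frontal = p$snsb_frontal,
      seed_params = seeds[i, 1], seed_stimuli = seeds[i, 2],
      seed_session = seeds[i, 3])
    if (keep_sessions) {
      sessions[[i]] <- synthesize_subject_session(
        p, seeds[i, ], ids[i], n_target, n_standard, isi_range_ms)
    }
  }
  subjects <- if (n == 0) {
    data.frame(subject_id = character(0), group = character(0))
  } else {
    do.call(rbind, subjects)
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("internal error: duplicate subject ids")
  }
  if (keep_sessions) names(sessions) <- ids
  names(params_list) <- ids
  digest <- fnv1a_hash(c(yaml::as.yaml(list(
    n_cn = n_cn, n_mci = n_mci, seed = as.integer(seed),
    n_target = n_target, n_standard = n_standard,
    isi_range_ms = isi_range_ms)),
    yaml::as.yaml(config)))
  structure(list(subjects = subjects, sessions = sessions,
                 params = params_list, config_digest = digest),
            class = "cohort_bundle")
}

#' Regenerate one subject's session from its seed triple
#'
#' Rebuilds a recording deterministically from the per-subject seeds stored
#' in a cohort's subject table (params / stimuli / session), so cohorts can
#' be stored as seeds instead of sample data.
#'
#' @param params The subject's `subject_params`.
#' @param seed_triple Integer vector: params, stimulus and session seeds.
#' @param subject_id Identifier for the recording.
#' @param n_target,n_standard,isi_range_ms Stimulus-sequence settings.
#' @return A `session_recording`.
#' @export
synthesize_subject_session <- function(params, seed_triple, subject_id,
                                       n_target = 64, n_standard = 256,
                                       isi_range_ms = c(900, 1100)) {
  stimuli <- generate_stimulus_sequence(n_target, n_standard, isi_range_ms,
                                        seed = seed_triple[2])
  synthesize_session(stimuli, params, seed = seed_triple[3],
                     subject_id = subject_id)
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$group == "CN"), " CN, ",
      sum(x$subjects$group == "MCI"), " MCI), config ",
      x$config_digest,
      if (is.null(x$sessions)) ", sessions not retained" else "",
      "\n", sep = "")
  invisible(x)
}
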