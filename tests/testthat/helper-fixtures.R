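# Shared fixtures: all built in code, no stored data.

# Calibration with per-parameter mean overrides applied to both groups;
# zero_sd makes every subject identical to the configured means.
calib_with <- function(overrides = list(), zero_sd = FALSE,
                       group = c("CN", "MCI")) {
  cfg <- default_calibration()
  for (g in group) {
    tab <- cfg$groups[[g]]
    if (zero_sd) tab$sd[] <- 0
    for (nm in names(overrides)) {
      i <- match(nm, tab$parameter)
      stopifnot(!is.na(i))
      tab$mean[i] <- overrides[[nm]]
    }
    cfg$groups[[g]] <- tab
  }
  cfg
}

# A deterministic "clean" subject: no background noise, perfect behavior.
noiseless_params <- function(amplitude = 8, latency = 400, width = 60,
                             group = "CN", seed = 1L) {
  simulate_subject_params(group, calib_with(list(
    p300_amplitude_uv = amplitude, p300_latency_ms = latency,
    p300_width_ms = width, noise_sd_uv = 0, alpha_power = 0,
    hit_rate = 1, commission_rate = 0), zero_sd = TRUE), seed = seed)
}

# Simulate and measure n subjects of one group; small sessions by default to
# keep unit tests quick.
measure_subjects <- function(group, n, seed0, config = default_calibration(),
                             n_target = 16, n_standard = 64,
                             isi_range_ms = c(500, 600)) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    p <- simulate_subject_params(group, config, seed = seed0 + 3 * i)
    s <- generate_stimulus_sequence(n_target, n_standard, isi_range_ms,
                                    seed = seed0 + 3 * i + 1)
    sess <- synthesize_session(s, p, seed = seed0 + 3 * i + 2,
                               subject_id = sprintf("%s%04d", group, i))
    extract_subject_features(sess, n_target = n_target,
                             n_standard = n_standard)
  }))
}

# Difference wave on the standard epoch axis from a function of time.
wave_on_axis <- function(f) {
  f(epoch_times())
}

# Hand-built trial records covering n_target + n_standard stimuli.
make_trials <- function(n_hit, n_omission, n_commission,
                        n_target = 64, n_standard = 256,
                        rt = rep(350, n_hit)) {
  kind <- c(rep("target", n_target), rep("standard", n_standard))
  classification <- c(rep("hit", n_hit), rep("omission", n_omission),
                      rep("hit", n_target - n_hit - n_omission),
                      rep("commission", n_commission),
                      rep("correct_rejection", n_standard - n_commission))
  # fill target slots: hits then omissions then hits again is fine for counts;
  # simpler: explicit classification vector of the right composition
  classification <- c(rep("hit", n_hit), rep("omission", n_omission),
                      rep("commission", n_commission),
                      rep("correct_rejection", n_standard - n_commission))
  stopifnot(n_hit + n_omission == n_target)
  rt_all <- c(rt, rep(NA_real_, n_omission), rep(300, n_commission),
              rep(NA_real_, n_standard - n_commission))
  data.frame(stimulus_index = seq_len(n_target + n_standard),
             onset_ms = 1000 * seq_len(n_target + n_standard),
             kind = c(rep("target", n_target), rep("standard", n_standard)),
             response_time_ms = rt_all,
             classification = classification)
}
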