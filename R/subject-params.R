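#' Default cohort calibration table
#'
#' Per-group generative parameter distributions (mean, SD, truncation bounds)
#' for simulated subjects. Demographics, neuropsychological scores and
#' behavioral-rate targets are taken directly from the reference cohort's
#' published group summary statistics (CN n = 239, MCI n = 95); evoked-
#' component parameters are calibrated so that the measured difference-wave
#' features land near the published feature means (amplitude and latency map
#' one-to-one; the component width and background-noise level jointly set the
#' zero-crossing span T2T1). Between-subject SDs of latent parameters are
#' deliberately smaller than the published feature SDs, which include
#' measurement noise.
#'
#' Structure: `list(groups = list(CN = <data.frame>, MCI = <data.frame>),
#' sex_male_prob = c(CN = ..., MCI = ...))`, each group data frame having
#' columns `parameter`, `mean`, `sd`, `lower`, `upper`.
#'
#' @return The calibration list described above.
#' @export
default_calibration <- function() {
  par_tab <- function(...) {
    rows <- list(...)
    out <- do.call(rbind, lapply(rows, function(r) {
      data.frame(parameter = r[[1]], mean = r[[2]], sd = r[[3]],
                 lower = r[[4]], upper = r[[5]])
    }))
    rownames(out) <- NULL
    out
  }
  cn <- par_tab(
    list("age_years",          72.17,   5.72,   40,    100),
    list("education_years",    10.58,   4.37,    0,     25),
    list("mmse",               27.62,   1.91,    0,     30),
    list("snsb_attention",      9.49,   2.21,    0,     20),
    list("snsb_language",       0.21,   0.25, -Inf,    Inf),
    list("snsb_visuospatial",   0.52,   0.37, -Inf,    Inf),
    list("snsb_memory",         0.32,   0.59, -Inf,    Inf),
    list("snsb_frontal",        0.22,   0.55, -Inf,    Inf),
    list("p300_amplitude_uv",   6.58,   2.50,  0.5,     30),
    list("p300_latency_ms",   388.35,  35.00,  300,    600),
    list("p300_width_ms",      34.00,  10.00,   15,    100),
    list("n100_amplitude_uv",  -3.00,   1.00,   -8,   -0.2),
    list("n100_latency_ms",   100.00,  12.00,   60,    160),
    list("n100_width_ms",      16.00,   0.00,    5,     40),
    list("hit_rate",          0.98800, 0.02230,  0,      1),
    list("commission_rate",   0.00594, 0.00856,  0,      1),
    list("rt_mu_ms",          312.80,  60.00,  150,    800),
    list("rt_sigma_ms",        85.00,  35.00,   10,    250),
    list("rt_tau_ms",          35.00,   0.00,    0,    200),
    list("noise_sd_uv",         8.00,   2.00,    1,     20),
    list("alpha_power",         4.00,   1.50,    0,     12)
  )
  mci <- cn
  set_par <- function(tab, name, mean = NULL, sd = NULL) {
    i <- match(name, tab$parameter)
    if (!is.null(mean)) tab$mean[i] <- mean
    if (!is.null(sd)) tab$sd[i] <- sd
    tab
  }
  mci <- set_par(mci, "age_years", 74.13, 6.27)
  mci <- set_par(mci, "education_years", 9.40, 4.78)
  mci <- set_par(mci, "mmse", 26.04, 2.54)
  mci <- set_par(mci, "snsb_attention", 8.38, 1.90)
  mci <- set_par(mci, "snsb_language", -0.13, 0.49)
  mci <- set_par(mci, "snsb_visuospatial", 0.00, 0.88)
  mci <- set_par(mci, "snsb_memory", -0.55, 0.67)
  mci <- set_par(mci, "snsb_frontal", -0.42, 0.71)
  mci <- set_par(mci, "p300_amplitude_uv", 7.99)
  mci <- set_par(mci, "p300_latency_ms", 393.35)
  mci <- set_par(mci, "p300_width_ms", 42.00)
  mci <- set_par(mci, "hit_rate", 0.96300, 0.07020)
  mci <- set_par(mci, "commission_rate", 0.01059, 0.01547)
  mci <- set_par(mci, "rt_mu_ms", 313.80, 70.00)
  mci <- set_par(mci, "rt_sigma_ms", 100.00, 37.00)
  list(groups = list(CN = cn, MCI = mci),
       sex_male_prob = c(CN = 99 / 239, MCI = 42 / 95))
}

#' Draw one subject's generative parameters
#'
#' Continuous parameters come from mean-calibrated truncated normals (the
#' truncated distribution's mean equals the configured target; a zero SD gives
#' exactly the configured mean); sex is Bernoulli with the configured
#' male probability. MCI defaults have a wider P300, lower hit rate, higher
#' commission rate and larger response-time variability than CN defaults.
#'
#' @param group `"CN"` or `"MCI"`.
#' @param config Calibration list as from [default_calibration()].
#' @param seed Integer seed.
#' @return A list of class `subject_params` with the group label, all
#'   generative parameters and `sex` (`"female"`/`"male"`).
#' @export
simulate_subject_params <- function(group = c("CN", "MCI"),
                                    config = default_calibration(),
                                    seed = 1L) {
  group <- match.arg(group)
  tab <- config$groups[[group]]
  if (is.null(tab)) {
    stop("calibration config has no parameter block for group ", group)
  }
  required <- c("age_years", "education_years", "mmse", "snsb_attention",
                "snsb_language", "snsb_visuospatial", "snsb_memory",
                "snsb_frontal", "p300_amplitude_uv", "p300_latency_ms",
                "p300_width_ms", "n100_amplitude_uv", "n100_latency_ms",
                "n100_width_ms", "hit_rate", "commission_rate", "rt_mu_ms",
                "rt_sigma_ms", "rt_tau_ms", "noise_sd_uv", "alpha_power")
  missing <- setdiff(required, tab$parameter)
  if (length(missing)) {
    stop("calibration config for group ", group, " is missing entries: ",
         paste(missing, collapse = ", "))
  }
  p_male <- config$sex_male_prob[[group]]
  if (is.null(p_male) || is.na(p_male)) {
    stop("calibration config is missing sex_male_prob for group ", group)
  }
  params <- withr::with_seed(as.integer(seed), {
    draws <- lapply(seq_len(nrow(tab)), function(i) {
      rtruncnorm_calibrated(1, tab$mean[i], tab$sd[i], tab$lower[i], tab$upper[i])
    })
    names(draws) <- tab$parameter
    draws$sex <- if (runif(1) < p_male) "male" else "female"
    draws
  })
  params <- params[c(required, "sex")]
  params$group <- group
  structure(params, class = "subject_params")
}
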