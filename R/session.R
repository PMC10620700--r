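# Synthesis of a single two-channel prefrontal oddball EEG session.

# 1/f ("pink") noise via spectral shaping: white Gaussian spectrum scaled by
# f^(-1/2), Hermitian-symmetrized, inverse FFT, normalized to unit SD.
pink_noise <- function(n) {
  if (n == 0) return(numeric(0))
  if (n == 1) return(rnorm(1))
  # generate at the next 2-3-5-smooth length (fast FFT) and truncate
  n_out <- n
  n <- stats::nextn(n, c(2, 3, 5))
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- f^(-0.5)
  re <- rnorm(nf) * amp
  im <- rnorm(nf) * amp
  if (n %% 2 == 0) im[nf] <- 0  # Nyquist bin must be real
  spec <- complex(real = c(0, re), imaginary = c(0, im))
  full <- c(spec, Conj(rev(spec[2:(nf + (n %% 2 == 1))])))
  # length bookkeeping: DC + nf positive bins + mirrored negative bins
  full <- full[seq_len(n)]
  x <- Re(fft(full, inverse = TRUE))[seq_len(n_out)] / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# Ex-Gaussian response-time draw (normal + exponential), rejected into
# `bounds` so every simulated press lands inside the response-attribution
# window (the untruncated tail mass beyond it is negligible at the defaults).
rexgauss <- function(n, mu, sigma, tau, bounds = c(100, 1000)) {
  out <- numeric(n)
  todo <- seq_len(n)
  for (tries in 1:100) {
    if (!length(todo)) break
    x <- rnorm(length(todo), mu, sigma)
    if (tau > 0) x <- x + rexp(length(todo), rate = 1 / tau)
    ok <- x > bounds[1] & x < bounds[2]
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) out[todo] <- mean(bounds)  # pathological parameters only
  out
}

gaussian_bump <- function(t, center, width, amplitude) {
  amplitude * exp(-((t - center)^2) / (2 * width^2))
}

#' Synthesize a two-channel oddball EEG session
#'
#' Each channel (Fp1, Fp2) is background EEG — pink noise scaled to
#' `noise_sd_uv` plus a 10 Hz alpha oscillation of amplitude `alpha_power`
#' with a random phase per channel — with the evoked response added on top:
#' a (negative) N100 Gaussian bump after every stimulus and a positive P300
#' Gaussian bump (amplitude `p300_amplitude_uv`, center `p300_latency_ms`
#' after onset, SD `p300_width_ms`) after every target. Both channels share
#' the evoked response and differ in background noise, so channel averaging
#' improves the evoked SNR. Key presses are generated per `hit_rate` /
#' `commission_rate` with ex-Gaussian latencies. Fully seed-deterministic.
#'
#' @param stimuli Stimulus event data frame from [generate_stimulus_sequence()].
#' @param params `subject_params` list (see [simulate_subject_params()]).
#' @param seed Integer seed.
#' @param subject_id Identifier stored in the recording.
#' @param sample_rate Sampling rate in Hz (250 by default).
#' @return A list of class `session_recording` with `subject_id`,
#'   `sample_rate`, channels `fp1`/`fp2` (microvolts, equal length, spanning
#'   all onsets plus an 800 ms tail), `stimuli` and `responses`
#'   (`data.frame` with strictly increasing `press_time_ms`).
#' @export
synthesize_session <- function(stimuli, params, seed = 1L,
                               subject_id = "S001", sample_rate = 250) {
  stopifnot(nrow(stimuli) > 0)
  dt_ms <- 1000 / sample_rate
  n <- ceiling((max(stimuli$onset_ms) + 810) / dt_ms) + 1
  t_ms <- (seq_len(n) - 1) * dt_ms

  # evoked response, shared by both channels; bumps have compact support and
  # are accumulated in place (no vector copies)
  evoked <- numeric(n)
  bump_centers <- c(stimuli$onset_ms + params$n100_latency_ms,
                    stimuli$onset_ms[stimuli$kind == "target"] +
                      params$p300_latency_ms)
  bump_widths <- c(rep(params$n100_width_ms, nrow(stimuli)),
                   rep(params$p300_width_ms, sum(stimuli$kind == "target")))
  bump_amps <- c(rep(params$n100_amplitude_uv, nrow(stimuli)),
                 rep(params$p300_amplitude_uv, sum(stimuli$kind == "target")))
  for (i in seq_along(bump_centers)) {
    if (bump_amps[i] == 0 || bump_widths[i] <= 0) next
    lo <- max(1L, floor((bump_centers[i] - 5 * bump_widths[i]) / dt_ms) + 1L)
    hi <- min(n, ceiling((bump_centers[i] + 5 * bump_widths[i]) / dt_ms) + 1L)
    idx <- lo:hi
    evoked[idx] <- evoked[idx] +
      gaussian_bump(t_ms[idx], bump_centers[i], bump_widths[i], bump_amps[i])
  }

  withr::with_seed(as.integer(seed), {
    channel <- function() {
      bg <- if (params$noise_sd_uv > 0) {
        pink_noise(n) * params$noise_sd_uv
      } else {
        numeric(n)
      }
      alpha <- if (params$alpha_power > 0) {
        params$alpha_power * sin(2 * pi * 10 * t_ms / 1000 + runif(1, 0, 2 * pi))
      } else {
        numeric(n)
      }
      bg + alpha + evoked
    }
    fp1 <- channel()
    fp2 <- channel()

    is_target <- stimuli$kind == "target"
    presses <- numeric(0)
    n_tgt <- sum(is_target)
    if (n_tgt > 0) {
      hit <- runif(n_tgt) < params$hit_rate
      if (any(hit)) {
        rt <- rexgauss(sum(hit), params$rt_mu_ms, params$rt_sigma_ms,
                       params$rt_tau_ms)
        presses <- c(presses, stimuli$onset_ms[is_target][hit] + rt)
      }
    }
    n_std <- sum(!is_target)
    if (n_std > 0) {
      com <- runif(n_std) < params$commission_rate
      if (any(com)) {
        rt <- rexgauss(sum(com), params$rt_mu_ms, params$rt_sigma_ms,
                       params$rt_tau_ms)
        presses <- c(presses, stimuli$onset_ms[!is_target][com] + rt)
      }
    }
  })
  presses <- round(sort(presses), 3)
  presses <- presses[c(TRUE, diff(presses) > 0)]  # enforce strict increase

  structure(list(subject_id = subject_id,
                 sample_rate = sample_rate,
                 fp1 = fp1, fp2 = fp2,
                 stimuli = stimuli,
                 responses = data.frame(press_time_ms = presses)),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat("<session_recording> ", x$subject_id, ": ",
      length(x$fp1), " samples/channel @ ", x$sample_rate, " Hz, ",
      nrow(x$stimuli), " stimuli (",
      sum(x$stimuli$kind == "target"), " targets), ",
      nrow(x$responses), " presses\n", sep = "")
  invisible(x)
}
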