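# Difference-wave ERP measurement.
#
# Epoch convention: half-open [-200, 800) ms at 250 Hz, i.e. 250 samples at
# 4 ms steps with stimulus onset at 0-based index 50; the baseline window
# [-200, 0) covers the first 50 samples. All reported times are in ms as real
# numbers (zero crossings and the fractional-area latency are interpolated to
# sub-sample precision).

#' Epoch time axis
#'
#' @param sample_rate Sampling rate in Hz.
#' @param epoch_ms Half-open epoch window in ms relative to stimulus onset.
#' @return Numeric vector of sample times in ms.
#' @export
epoch_times <- function(sample_rate = 250, epoch_ms = c(-200, 800)) {
  dt <- 1000 / sample_rate
  seq(epoch_ms[1], epoch_ms[2] - dt, by = dt)
}

#' Average the two prefrontal channels
#'
#' @param recording A `session_recording`.
#' @return Pointwise arithmetic mean of Fp1 and Fp2 as a numeric vector.
#' @export
average_channels <- function(recording) {
  if (length(recording$fp1) != length(recording$fp2)) {
    stop("channel length mismatch: fp1 has ", length(recording$fp1),
         " samples, fp2 has ", length(recording$fp2))
  }
  (recording$fp1 + recording$fp2) / 2
}

#' Attribute key presses to stimuli and classify trials
#'
#' Each press is attributed to the most recent stimulus whose onset precedes
#' it by a latency inside `window_ms` (inclusive); a stimulus takes at most
#' one press (the first wins; later presses mapping to an already-answered
#' stimulus are stray, as are presses with no qualifying stimulus). Targets
#' are then hits (answered) or omissions; standards are commissions (answered)
#' or correct rejections.
#'
#' @param stimuli Stimulus data frame (`onset_ms`, `kind`), time-sorted.
#' @param responses Response data frame (`press_time_ms`), time-sorted, or a
#'   numeric vector of press times.
#' @param window_ms Attribution window `[lo, hi]` in ms after stimulus onset.
#' @return A data frame of trial records (`stimulus_index`, `onset_ms`,
#'   `kind`, `response_time_ms`, `classification`) with attribute
#'   `n_stray_presses`.
#' @export
attribute_responses <- function(stimuli, responses, window_ms = c(100, 1000)) {
  press <- if (is.data.frame(responses)) responses$press_time_ms else responses
  stopifnot(!is.unsorted(stimuli$onset_ms, strictly = TRUE),
            !is.unsorted(press))
  n <- nrow(stimuli)
  rt <- rep(NA_real_, n)
  stray <- 0L
  for (p in press) {
    lat <- p - stimuli$onset_ms
    ok <- which(lat >= window_ms[1] & lat <= window_ms[2])
    if (!length(ok)) {
      stray <- stray + 1L
      next
    }
    i <- max(ok)  # most recent qualifying stimulus
    if (is.na(rt[i])) {
      rt[i] <- lat[i]
    } else {
      stray <- stray + 1L  # stimulus already answered; no cascading
    }
  }
  classification <- ifelse(stimuli$kind == "target",
                           ifelse(is.na(rt), "omission", "hit"),
                           ifelse(is.na(rt), "correct_rejection", "commission"))
  out <- data.frame(stimulus_index = seq_len(n),
                    onset_ms = stimuli$onset_ms, kind = stimuli$kind,
                    response_time_ms = rt, classification = classification)
  attr(out, "n_stray_presses") <- stray
  out
}

#' Extract correct-trial epochs for one condition
#'
#' Cuts `[-200, 800)` ms windows (250 samples, onset at 0-based index 50)
#' around the correct trials of the requested condition: hits for targets,
#' correct rejections for standards. Commissions and omissions are excluded
#' from both conditions. Trials whose window exceeds the recording are skipped
#' with a warning.
#'
#' @param signal Channel-averaged sample vector.
#' @param trials Trial records from [attribute_responses()].
#' @param condition `"standard"` or `"target"`.
#' @param sample_rate Sampling rate in Hz.
#' @param epoch_ms Epoch window in ms (half-open).
#' @return Matrix with one row per epoch (0 rows if none usable).
#' @export
extract_epochs <- function(signal, trials, condition = c("standard", "target"),
                           sample_rate = 250, epoch_ms = c(-200, 800)) {
  condition <- match.arg(condition)
  wanted <- if (condition == "target") "hit" else "correct_rejection"
  keep <- trials[trials$classification == wanted, , drop = FALSE]
  dt <- 1000 / sample_rate
  n_samp <- round((epoch_ms[2] - epoch_ms[1]) / dt)
  n_pre <- round(-epoch_ms[1] / dt)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(keep))) {
    onset_idx <- round(keep$onset_ms[i] / dt)  # 0-based sample at onset
    first <- onset_idx - n_pre + 1L            # 1-based R index
    last <- first + n_samp - 1L
    if (first < 1L || last > length(signal)) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- signal[first:last]
  }
  if (skipped > 0L) {
    warning(skipped, " ", condition,
            " trial(s) skipped: epoch window exceeds recording bounds")
  }
  if (!length(rows)) {
    return(matrix(numeric(0), nrow = 0, ncol = n_samp))
  }
  do.call(rbind, rows)
}

#' Baseline-correct epochs
#'
#' Subtracts each epoch's mean over the pre-stimulus baseline (default
#' `[-200, 0)` ms, the first 50 samples) from the whole epoch.
#'
#' @param epochs Epoch matrix (rows = epochs) or a single numeric vector.
#' @param sample_rate,epoch_ms,baseline_ms Axis and baseline definition.
#' @return Object of the same shape, baseline-corrected.
#' @export
baseline_correct <- function(epochs, sample_rate = 250,
                             epoch_ms = c(-200, 800),
                             baseline_ms = c(-200, 0)) {
  tt <- epoch_times(sample_rate, epoch_ms)
  base_idx <- which(tt >= baseline_ms[1] & tt < baseline_ms[2])
  if (is.matrix(epochs)) {
    if (nrow(epochs) == 0) return(epochs)
    epochs - rowMeans(epochs[, base_idx, drop = FALSE])
  } else {
    epochs - mean(epochs[base_idx])
  }
}

#' Centered moving-average smoothing
#'
#' Order-nine (by default) centered moving average with reflection padding
#' (the first interior samples mirrored around each end, edge excluded), so
#' the output has the trace's length and a constant trace is unchanged.
#'
#' @param trace Numeric vector.
#' @param taps Odd number of taps (>= 1).
#' @return Smoothed vector of the same length.
#' @export
smooth_trace <- function(trace, taps = 9L) {
  if (taps %% 2 == 0 || taps < 1) {
    stop("taps must be odd and >= 1, got ", taps)
  }
  if (taps == 1) return(trace)
  h <- (taps - 1L) / 2L
  n <- length(trace)
  if (n < h + 1L) stop("trace too short for ", taps, "-tap smoothing")
  padded <- c(trace[(h + 1L):2L], trace, trace[(n - 1L):(n - h)])
  out <- stats::filter(padded, rep(1 / taps, taps), sides = 2)
  as.numeric(out[(h + 1L):(h + n)])
}

#' Average epochs into an ERP trace
#'
#' @param epochs Epoch matrix with at least one row.
#' @return Pointwise mean across epochs.
#' @export
average_erp <- function(epochs) {
  if (!is.matrix(epochs)) epochs <- matrix(epochs, nrow = 1)
  if (nrow(epochs) == 0) {
    stop("no epochs to average: subject has no correct trials in this condition")
  }
  colMeans(epochs)
}

#' Difference wave (target minus standard)
#'
#' @param target_avg,standard_avg Averaged ERP traces on the same axis.
#' @return Pointwise `target_avg - standard_avg`.
#' @export
difference_wave <- function(target_avg, standard_avg) {
  if (length(target_avg) != length(standard_avg)) {
    stop("trace length mismatch: target has ", length(target_avg),
         ", standard has ", length(standard_avg), " samples")
  }
  target_avg - standard_avg
}

#' Locate the P300 peak of the difference wave
#'
#' The peak is the global maximum of the difference wave within the search
#' window (default 300--600 ms, inclusive); no prominence rule is applied.
#'
#' @param difference Difference wave on the standard epoch axis.
#' @param sample_rate,epoch_ms Axis definition.
#' @param window_ms Search window in ms.
#' @return List with `AMP` (microvolts), `LAT` (ms) and `peak_found`
#'   (`FALSE` when the maximum is non-positive).
#' @export
locate_p300 <- function(difference, sample_rate = 250, epoch_ms = c(-200, 800),
                        window_ms = c(300, 600)) {
  tt <- epoch_times(sample_rate, epoch_ms)
  idx <- which(tt >= window_ms[1] & tt <= window_ms[2])
  k <- idx[which.max(difference[idx])]
  list(AMP = difference[k], LAT = tt[k], peak_found = difference[k] > 0)
}

#' Zero crossings bracketing the P300 peak
#'
#' T1 is the nearest sign change of the difference wave at or before the peak,
#' T2 the nearest after it; crossing times are linearly interpolated between
#' samples, searched over the whole epoch (T1 may precede the 300 ms window
#' edge). A sample that is exactly zero is itself the crossing (nearest the
#' peak wins). `valid` is `FALSE` when either crossing is absent within the
#' epoch; such subjects lack a measurable component and are excluded
#' downstream.
#'
#' @param difference Difference wave on the standard epoch axis.
#' @param LAT Peak latency in ms (from [locate_p300()], which must have found
#'   a positive peak).
#' @param sample_rate,epoch_ms Axis definition.
#' @return List with `T1`, `T2` (ms, `NA` when absent) and `valid`.
#' @export
zero_crossings <- function(difference, LAT, sample_rate = 250,
                           epoch_ms = c(-200, 800)) {
  tt <- epoch_times(sample_rate, epoch_ms)
  peak <- which.min(abs(tt - LAT))
  if (difference[peak] <= 0) {
    stop("zero_crossings requires a positive peak at LAT")
  }
  interp_zero <- function(i, j) {
    # crossing between samples i and j (d[i], d[j] of opposite strict sign)
    tt[i] + (tt[j] - tt[i]) * (0 - difference[i]) / (difference[j] - difference[i])
  }
  t1 <- NA_real_
  i <- peak - 1L
  while (i >= 1L) {
    if (difference[i] == 0) { t1 <- tt[i]; break }
    if (difference[i] < 0) { t1 <- interp_zero(i, i + 1L); break }
    i <- i - 1L
  }
  t2 <- NA_real_
  j <- peak + 1L
  while (j <= length(difference)) {
    if (difference[j] == 0) { t2 <- tt[j]; break }
    if (difference[j] < 0) { t2 <- interp_zero(j - 1L, j); break }
    j <- j + 1L
  }
  list(T1 = t1, T2 = t2, valid = !is.na(t1) && !is.na(t2))
}

# Piecewise-linear view of the sampled difference wave between two time
# points: knot times, knot values (endpoint values linearly interpolated).
pl_knots <- function(difference, tt, t_from, t_to) {
  val_at <- function(t) {
    i <- findInterval(t, tt)
    if (i >= length(tt)) return(difference[length(tt)])
    if (i < 1) return(difference[1])
    w <- (t - tt[i]) / (tt[i + 1] - tt[i])
    (1 - w) * difference[i] + w * difference[i + 1]
  }
  inner <- which(tt > t_from & tt < t_to)
  kt <- c(t_from, tt[inner], t_to)
  kv <- c(val_at(t_from), difference[inner], val_at(t_to))
  list(t = kt, v = kv)
}

#' Area under the curve and 50% fractional-area latency
#'
#' Integrates the difference wave over `[T1, T2]` by exact trapezoids on the
#' piecewise-linear interpolant (partial end intervals included), giving the
#' AUC in microvolt-milliseconds. FAL is the time at which the cumulative area
#' from T1 reaches half the AUC; within a sample interval the cumulative area
#' is quadratic in time and the half-area crossing is solved exactly, so
#' analytic waveforms (triangles, rectangles) are reproduced to rounding
#' error.
#'
#' @param difference Difference wave on the standard epoch axis.
#' @param T1,T2 Integration bounds in ms, `T1 < T2`.
#' @param sample_rate,epoch_ms Axis definition.
#' @return List with `AUC` (microvolt-ms), `FAL` (ms) and `valid`
#'   (`FALSE` when `AUC <= 0`, in which case `FAL` is `NA`).
#' @export
area_features <- function(difference, T1, T2, sample_rate = 250,
                          epoch_ms = c(-200, 800)) {
  stopifnot(T1 < T2)
  tt <- epoch_times(sample_rate, epoch_ms)
  k <- pl_knots(difference, tt, T1, T2)
  seg_w <- diff(k$t)
  seg_area <- seg_w * (head_(k$v) + tail_(k$v)) / 2
  auc <- sum(seg_area)
  if (auc <= 0) {
    return(list(AUC = auc, FAL = NA_real_, valid = FALSE))
  }
  target <- auc / 2
  cum <- c(0, cumsum(seg_area))
  s <- which(cum[-1] >= target)[1]  # segment containing the half-area point
  ya <- k$v[s]; yb <- k$v[s + 1]; h <- seg_w[s]
  rem <- target - cum[s]
  # solve ya*u + (yb-ya)*u^2/(2h) = rem for u in [0, h]
  a2 <- (yb - ya) / (2 * h)
  if (abs(a2) < 1e-12 * max(1, abs(ya))) {
    u <- if (ya == 0) h else rem / ya
  } else {
    disc <- ya^2 + 4 * a2 * rem
    roots <- (-ya + c(-1, 1) * sqrt(max(disc, 0))) / (2 * a2)
    inok <- roots[roots >= -1e-9 & roots <= h + 1e-9]
    u <- if (length(inok)) min(max(inok[1], 0), h) else h
  }
  list(AUC = auc, FAL = k$t[s] + u, valid = TRUE)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Derived P300 interval measures
#'
#' Exact subtractions: component duration `T2T1 = T2 - T1`, early half
#' `FALT1 = FAL - T1`, late half `T2FAL = T2 - FAL`; additivity
#' `T2T1 = FALT1 + T2FAL` holds to machine precision.
#'
#' @param T1,T2,FAL Times in ms with `T1 < FAL < T2`.
#' @return List with `T2T1`, `FALT1`, `T2FAL`.
#' @export
derived_intervals <- function(T1, T2, FAL) {
  if (!(T1 < FAL && FAL < T2)) {
    stop("ordering violation: need T1 < FAL < T2, got T1=", T1,
         " FAL=", FAL, " T2=", T2)
  }
  list(T2T1 = T2 - T1, FALT1 = FAL - T1, T2FAL = T2 - FAL)
}

#' Extract the nine difference-wave ERP measures from a session
#'
#' Full measurement pipeline: channel averaging, response attribution,
#' epoching of correct trials, baseline correction, per-condition averaging,
#' order-nine smoothing of each averaged trace, difference wave
#' (target minus standard), then peak, zero crossings, area measures and
#' derived intervals. `valid` reflects every gate; when invalid, `reason` is
#' one of `no_correct_trials`, `no_peak`, `no_crossings`, `nonpositive_auc`.
#'
#' @param recording A `session_recording`.
#' @param options ERP measurement options, see [erp_options()].
#' @return One-row `data.frame`: `subject_id`, `valid`, `reason`, the nine
#'   measures (`AMP`, `LAT`, `FAL`, `T1`, `T2`, `AUC`, `T2T1`, `FALT1`,
#'   `T2FAL`) and trial counts `n_target_trials`, `n_standard_trials`.
#' @export
extract_erp_features <- function(recording, options = erp_options()) {
  na_row <- function(reason, n_t = 0L, n_s = 0L) {
    data.frame(subject_id = recording$subject_id, valid = FALSE,
               reason = reason, AMP = NA_real_, LAT = NA_real_,
               FAL = NA_real_, T1 = NA_real_, T2 = NA_real_, AUC = NA_real_,
               T2T1 = NA_real_, FALT1 = NA_real_, T2FAL = NA_real_,
               n_target_trials = n_t, n_standard_trials = n_s)
  }
  sr <- recording$sample_rate
  signal <- average_channels(recording)
  trials <- attribute_responses(recording$stimuli, recording$responses,
                                options$response_window_ms)
  ep_t <- extract_epochs(signal, trials, "target", sr, options$epoch_ms)
  ep_s <- extract_epochs(signal, trials, "standard", sr, options$epoch_ms)
  if (nrow(ep_t) == 0 || nrow(ep_s) == 0) {
    return(na_row("no_correct_trials", nrow(ep_t), nrow(ep_s)))
  }
  ep_t <- baseline_correct(ep_t, sr, options$epoch_ms, options$baseline_ms)
  ep_s <- baseline_correct(ep_s, sr, options$epoch_ms, options$baseline_ms)
  tgt <- smooth_trace(average_erp(ep_t), options$smooth_taps)
  std <- smooth_trace(average_erp(ep_s), options$smooth_taps)
  d <- difference_wave(tgt, std)

  peak <- locate_p300(d, sr, options$epoch_ms, options$window_ms)
  out <- na_row("", nrow(ep_t), nrow(ep_s))
  out$AMP <- peak$AMP
  out$LAT <- peak$LAT
  if (!peak$peak_found) {
    out$reason <- "no_peak"
    return(out)
  }
  cross <- zero_crossings(d, peak$LAT, sr, options$epoch_ms)
  if (!cross$valid) {
    out$reason <- "no_crossings"
    return(out)
  }
  out$T1 <- cross$T1
  out$T2 <- cross$T2
  area <- area_features(d, cross$T1, cross$T2, sr, options$epoch_ms)
  out$AUC <- area$AUC
  if (!area$valid) {
    out$reason <- "nonpositive_auc"
    return(out)
  }
  out$FAL <- area$FAL
  iv <- derived_intervals(cross$T1, cross$T2, area$FAL)
  out$T2T1 <- iv$T2T1
  out$FALT1 <- iv$FALT1
  out$T2FAL <- iv$T2FAL
  out$valid <- TRUE
  out
}

#' ERP measurement options
#'
#' Defaults are the recording/measurement parameters of the analysis:
#' `[-200, 800)` ms epochs, `[-200, 0)` ms baseline, 300--600 ms peak search
#' window, 9-tap moving average, `[100, 1000]` ms response-attribution window.
#'
#' @param epoch_ms,baseline_ms,window_ms,smooth_taps,response_window_ms See
#'   the individual operations.
#' @return Named list of options.
#' @export
erp_options <- function(epoch_ms = c(-200, 800), baseline_ms = c(-200, 0),
                        window_ms = c(300, 600), smooth_taps = 9L,
                        response_window_ms = c(100, 1000)) {
  list(epoch_ms = epoch_ms, baseline_ms = baseline_ms, window_ms = window_ms,
       smooth_taps = smooth_taps, response_window_ms = response_window_ms)
}
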