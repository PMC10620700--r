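#' Compute the six task-performance measures
#'
#' From classified trials: `NI` = number of commission errors (presses to
#' standards); omissions = unanswered targets; correct responses = hits.
#' `ER` = (NI + omissions) / hits; `ACC` = 100 * hits / n_target (percent);
#' `WER` = mean of the two per-class error rates,
#' (NI / n_standard + omissions / n_target) / 2; `RT` = mean hit latency (ms);
#' `RTSD` = sample (n-1) standard deviation of hit latencies (ms, `NA` with
#' fewer than 2 hits). A subject with zero hits has an undefined `ER` and is
#' flagged invalid (mirroring the exclusion of non-responders).
#'
#' @param trials Trial records from [attribute_responses()].
#' @param n_target,n_standard Stimulus counts presented (the trials must cover
#'   all of them).
#' @return One-row `data.frame`: `NI`, `ER`, `ACC`, `WER`, `RT`, `RTSD`,
#'   `n_hits`, `n_omissions`, `behavioral_valid`.
#' @export
compute_behavioral <- function(trials, n_target = 64, n_standard = 256) {
  if (nrow(trials) != n_target + n_standard ||
      sum(trials$kind == "target") != n_target) {
    stop("trials do not cover the stated stimulus counts (",
         n_target, " targets + ", n_standard, " standards)")
  }
  hits <- sum(trials$classification == "hit")
  omissions <- sum(trials$classification == "omission")
  ni <- sum(trials$classification == "commission")
  rts <- trials$response_time_ms[trials$classification == "hit"]
  valid <- hits > 0
  data.frame(
    NI = ni,
    ER = if (valid) (ni + omissions) / hits else NA_real_,
    ACC = 100 * hits / n_target,
    WER = (ni / n_standard + omissions / n_target) / 2,
    RT = if (hits >= 1) mean(rts) else NA_real_,
    RTSD = if (hits >= 2) stats::sd(rts) else NA_real_,
    n_hits = hits, n_omissions = omissions,
    behavioral_valid = valid)
}

#' Expected error measures at given performance rates
#'
#' Evaluates the adopted ER/WER/ACC formulas at a subject's expected
#' performance (mean commission count and hit percentage) rather than at
#' integer trial counts; used to check that the adopted reconstructions of
#' the weighted error rate and error ratio reproduce the reference cohort's
#' printed group means.
#'
#' @param mean_ni Expected commission count.
#' @param acc_pct Hit percentage among targets.
#' @param n_target,n_standard Stimulus counts.
#' @return List with `ER`, `WER`, `ACC`, `hits`, `omissions`.
#' @export
reconstruct_error_measures <- function(mean_ni, acc_pct, n_target = 64,
                                       n_standard = 256) {
  hits <- acc_pct / 100 * n_target
  omissions <- n_target - hits
  list(ER = (mean_ni + omissions) / hits,
       WER = (mean_ni / n_standard + omissions / n_target) / 2,
       ACC = acc_pct, hits = hits, omissions = omissions)
}
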