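#' Generate an auditory-oddball stimulus sequence
#'
#' Builds the event list of a single active-oddball session: rare 2,000 Hz
#' target tones interleaved among frequent 750 Hz standard tones (the default
#' 64/256 split gives the classic 1/5 target ratio). Target positions are
#' uniformly random among arrangements with no two consecutive targets (the
#' usual constraint in oddball practice; disable with
#' `allow_consecutive_targets = TRUE` for a fully random shuffle).
#' Inter-stimulus onset intervals are drawn uniformly from `isi_range_ms`.
#'
#' @param n_target,n_standard Numbers of target and standard tones.
#' @param isi_range_ms Length-2 numeric, uniform inter-stimulus onset interval
#'   bounds in ms. A degenerate range (equal bounds) gives fixed spacing.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param allow_consecutive_targets Drop the no-two-consecutive-targets rule.
#' @return A `data.frame` with columns `onset_ms` (strictly increasing),
#'   `kind` (`"standard"`/`"target"`) and `tone_frequency_hz` (750/2000).
#' @export
generate_stimulus_sequence <- function(n_target = 64, n_standard = 256,
                                       isi_range_ms = c(900, 1100),
                                       seed = 1L,
                                       allow_consecutive_targets = FALSE) {
  stopifnot(n_target >= 0, n_standard >= 0,
            length(isi_range_ms) == 2, all(isi_range_ms > 0),
            isi_range_ms[1] <= isi_range_ms[2])
  if (!allow_consecutive_targets && n_target > n_standard + 1) {
    stop("cannot place ", n_target, " targets among ", n_standard,
         " standards without consecutive targets")
  }
  n <- n_target + n_standard
  if (n == 0) {
    return(data.frame(onset_ms = numeric(0), kind = character(0),
                      tone_frequency_hz = numeric(0)))
  }
  withr::with_seed(as.integer(seed), {
    if (allow_consecutive_targets) {
      kind <- sample(c(rep("target", n_target), rep("standard", n_standard)))
    } else {
      # one target at most into each of the n_standard + 1 slots around the
      # standards: uniform over valid arrangements
      slots <- sort(sample.int(n_standard + 1, n_target))
      kind <- character(0)
      for (g in seq_len(n_standard + 1)) {
        if (g %in% slots) kind <- c(kind, "target")
        if (g <= n_standard) kind <- c(kind, "standard")
      }
    }
    isi <- runif(n, isi_range_ms[1], isi_range_ms[2])
    onset <- round(cumsum(isi), 3)
  })
  data.frame(onset_ms = onset, kind = kind,
             tone_frequency_hz = ifelse(kind == "target", 2000, 750))
}
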