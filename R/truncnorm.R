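# Mean-calibrated truncated normal draws.
#
# Subject-level parameters are drawn from normal distributions truncated to
# their physical ranges (rates in [0,1], widths > 0, ...). Plain truncation
# shifts the mean away from the configured target whenever a bound is within a
# couple of SDs (e.g. a hit rate of 0.988 with SD 0.022 against the upper
# bound 1), so the location parameter is solved numerically so that the
# truncated distribution's mean equals the configured target. Where truncation
# is negligible the adjustment is essentially zero.

truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  # window mass computed in whichever tail keeps precision, so the formula
  # stays accurate when the window sits many SDs from mu
  z <- if (a > 0) {
    pnorm(a, lower.tail = FALSE) - pnorm(b, lower.tail = FALSE)
  } else {
    pnorm(b) - pnorm(a)
  }
  da <- if (is.finite(a)) dnorm(a) else 0
  db <- if (is.finite(b)) dnorm(b) else 0
  if (z <= 0) {
    # window beyond double-precision tail mass: mean collapses to the bound
    return(if (a > 0) lower else upper)
  }
  mu + sd * (da - db) / z
}

# Solve for the location whose truncated mean equals `target`.
truncnorm_location <- function(target, sd, lower, upper) {
  if (sd == 0) {
    return(target)
  }
  if (target <= lower || target >= upper) {
    stop("target mean ", target, " not attainable inside [", lower, ", ", upper, "]")
  }
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target
  span <- 10 * sd
  uniroot(f, lower = target - span, upper = target + span,
          tol = 1e-10 * max(1, abs(target)))$root
}

# Draw n values whose population mean equals `mean` after truncation to
# [lower, upper]. sd = 0 degenerates to the constant `mean`.
rtruncnorm_calibrated <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper || sd == 0)
  if (sd == 0) {
    return(rep(mean, n))
  }
  mu <- truncnorm_location(mean, sd, lower, upper)
  pa <- pnorm(lower, mu, sd)
  pb <- pnorm(upper, mu, sd)
  qnorm(pa + runif(n) * (pb - pa), mu, sd)
}
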