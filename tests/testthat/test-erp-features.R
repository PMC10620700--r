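test_that("channel averaging is the exact pointwise mean", {
  rec <- list(fp1 = c(1, 1, 1), fp2 = c(3, 3, 3))
  expect_equal(average_channels(rec), c(2, 2, 2))
  rec2 <- list(fp1 = c(0.5, -1, 2), fp2 = c(0.5, -1, 2))
  expect_equal(average_channels(rec2), rec2$fp1)
  withr::with_seed(1, {
    a <- rnorm(100); b <- rnorm(100)
  })
  expect_equal(average_channels(list(fp1 = a, fp2 = b)),
               vapply(1:100, function(i) mean(c(a[i], b[i])), numeric(1)))
  expect_error(average_channels(list(fp1 = 1:3, fp2 = 1:4)), "mismatch")
})

test_that("response attribution classifies hits, omissions, commissions, strays", {
  stim <- data.frame(onset_ms = c(0, 1000), kind = c("target", "standard"))
  tr <- attribute_responses(stim, c(348), c(100, 1000))
  expect_equal(tr$classification, c("hit", "correct_rejection"))
  expect_equal(tr$response_time_ms[1], 348)

  tr <- attribute_responses(stim, numeric(0), c(100, 1000))
  expect_equal(tr$classification, c("omission", "correct_rejection"))

  stim2 <- data.frame(onset_ms = 0, kind = "standard")
  tr <- attribute_responses(stim2, 300, c(100, 1000))
  expect_equal(tr$classification, "commission")
  tr <- attribute_responses(stim2, 50, c(100, 1000))
  expect_equal(tr$classification, "correct_rejection")
  expect_equal(attr(tr, "n_stray_presses"), 1L)

  # boundary enumeration: presses to a single standard at 0 with window
  # [100, 1000]; inclusive bounds, anything outside is stray
  for (p in c(99.9, 100, 500, 1000, 1000.1)) {
    tr <- attribute_responses(stim2, p, c(100, 1000))
    inside <- p >= 100 && p <= 1000
    expect_equal(tr$classification == "commission", inside, label = p)
  }

  # a second press to an answered stimulus is stray, first wins
  tr <- attribute_responses(stim, c(200, 400), c(100, 1000))
  expect_equal(tr$response_time_ms[1], 200)
  expect_equal(attr(tr, "n_stray_presses"), 1L)

  # attribution picks the most recent qualifying stimulus
  stim3 <- data.frame(onset_ms = c(0, 900), kind = c("target", "target"))
  tr <- attribute_responses(stim3, 950, c(100, 1000))  # 50 ms after 2nd
  expect_equal(tr$classification, c("hit", "omission"))
  expect_equal(tr$response_time_ms[1], 950)
})

test_that("epoch extraction uses exact index arithmetic on correct trials only", {
  n <- 2000
  signal <- seq_len(n)  # signal value = 1-based sample index
  stim <- data.frame(onset_ms = 1000 * 4, kind = "target")  # 0-based sample 1000
  trials <- data.frame(stimulus_index = 1, onset_ms = stim$onset_ms,
                       kind = "target", response_time_ms = 350,
                       classification = "hit")
  ep <- extract_epochs(signal, trials, "target")
  expect_equal(dim(ep), c(1, 250))
  expect_equal(ep[1, ], as.numeric(951:1200))  # 0-based samples 950..1199

  # commissions belong to neither condition
  trials2 <- data.frame(stimulus_index = 1, onset_ms = 4000, kind = "standard",
                        response_time_ms = 300, classification = "commission")
  expect_equal(nrow(extract_epochs(signal, trials2, "standard")), 0)
  expect_equal(nrow(extract_epochs(signal, trials2, "target")), 0)

  # constant signal gives constant epochs; out-of-bounds trials are skipped
  trials3 <- rbind(trials, within(trials, onset_ms <- 40))
  expect_warning(ep3 <- extract_epochs(rep(7, n), trials3, "target"),
                 "skipped")
  expect_equal(ep3, matrix(7, 1, 250))
})

test_that("baseline correction subtracts the pre-stimulus mean exactly", {
  expect_equal(baseline_correct(rep(3.5, 250)), rep(0, 250))
  withr::with_seed(2, e <- rnorm(250))
  tt <- epoch_times()
  oracle <- e - mean(e[tt >= -200 & tt < 0])
  expect_equal(baseline_correct(e), oracle)
  expect_lt(abs(mean(baseline_correct(e)[tt < 0])), 1e-9)
  # matrix form agrees with row-wise application
  m <- rbind(e, 2 * e)
  expect_equal(baseline_correct(m)[2, ], baseline_correct(2 * e),
               ignore_attr = TRUE)
})

test_that("nine-tap smoothing matches the sliding-window oracle", {
  expect_equal(smooth_trace(rep(2.5, 50)), rep(2.5, 50))
  imp <- rep(0, 51); imp[26] <- 1
  sm <- smooth_trace(imp)
  expect_equal(sm[22:30], rep(1 / 9, 9))
  expect_equal(sum(sm), 1)
  withr::with_seed(3, x <- rnorm(80))
  sm <- smooth_trace(x)
  for (i in 5:76) {
    expect_equal(sm[i], mean(x[(i - 4):(i + 4)]), tolerance = 1e-12)
  }
  expect_error(smooth_trace(x, taps = 8), "odd")
})

test_that("epoch averaging and the difference wave are exact linear ops", {
  withr::with_seed(4, e <- matrix(rnorm(5 * 250), 5))
  expect_equal(average_erp(e[1, , drop = FALSE]), e[1, ])
  expect_equal(average_erp(rbind(e[1, ], -e[1, ])), rep(0, 250))
  expect_equal(average_erp(e),
               vapply(1:250, function(j) mean(e[, j]), numeric(1)))
  expect_error(average_erp(e[0, , drop = FALSE]), "no epochs")

  t_avg <- average_erp(e[1:3, ]); s_avg <- average_erp(e[3:5, ])
  expect_equal(difference_wave(t_avg, t_avg), rep(0, 250))
  expect_equal(difference_wave(t_avg, rep(0, 250)), t_avg)
  expect_equal(difference_wave(t_avg, s_avg), t_avg - s_avg)
  expect_error(difference_wave(1:10, 1:9), "mismatch")

  # difference of averages equals average of per-trial differences at
  # matched trial counts (linearity of the pipeline)
  d_of_avg <- difference_wave(average_erp(e[1:2, ]), average_erp(e[3:4, ]))
  avg_of_d <- average_erp(rbind(e[1, ] - e[3, ], e[2, ] - e[4, ]))
  expect_equal(d_of_avg, avg_of_d, tolerance = 1e-12)
})

test_that("peak location matches an exhaustive scan of the search window", {
  tt <- epoch_times()
  bump <- 5 * exp(-((tt - 400)^2) / (2 * 40^2))
  pk <- locate_p300(bump)
  expect_equal(pk$AMP, 5)
  expect_equal(pk$LAT, 400)
  expect_true(pk$peak_found)

  pk <- locate_p300(rep(-1, 250) - tt / 1000)
  expect_false(pk$peak_found)

  sine <- sin(2 * pi * tt / 230 + 0.7)
  idx <- which(tt >= 300 & tt <= 600)
  best <- idx[which.max(sine[idx])]  # brute force over window samples
  pk <- locate_p300(sine)
  expect_equal(pk$LAT, tt[best])
  expect_equal(pk$AMP, sine[best])
})

test_that("zero crossings are linearly interpolated with machine-zero residual", {
  tt <- epoch_times()
  # positive half-sine supported on [252, 552] (grid-aligned endpoints)
  half <- ifelse(tt >= 252 & tt <= 552, sin(pi * (tt - 252) / 300), -0.3)
  pk <- locate_p300(half)
  zc <- zero_crossings(half, pk$LAT)
  expect_true(zc$valid)
  expect_equal(zc$T1, 252)  # exact-zero sample taken as the crossing
  expect_equal(zc$T2, 552, tolerance = 1e-9)

  # the worked interpolation example: (296, -1) and (300, +3) cross at 297
  d <- c(rep(-1, 125), rep(3, 125))
  zc <- zero_crossings(d, 300)
  expect_equal(zc$T1, 297)

  # interpolated crossing has a numerically zero wave value
  withr::with_seed(5, nz <- smooth_trace(rnorm(250)) +
                     2 * exp(-((tt - 420)^2) / (2 * 50^2)))
  pk <- locate_p300(nz)
  if (pk$peak_found) {
    zc <- zero_crossings(nz, pk$LAT)
    if (zc$valid) {
      at <- function(t) approx(tt, nz, xout = t)$y
      expect_lt(abs(at(zc$T1)), 1e-9)
      expect_lt(abs(at(zc$T2)), 1e-9)
    }
  }

  # an everywhere-positive difference has no crossings
  zc <- zero_crossings(abs(sin(tt / 90)) + 0.1, 400)
  expect_false(zc$valid)
})

test_that("area and fractional-area latency reproduce closed forms", {
  tt <- epoch_times()
  tri <- pmax(0, 10 * (1 - abs(tt - 400) / 100))
  a <- area_features(tri, 300, 500)
  expect_equal(a$AUC, 1000, tolerance = 1e-9)
  expect_equal(a$FAL, 400, tolerance = 1e-9)

  rect <- ifelse(tt >= 300 & tt <= 500, 4, 0)
  a <- area_features(rect, 300, 500)
  expect_equal(a$AUC, 800, tolerance = 1e-9)
  expect_equal(a$FAL, 400, tolerance = 1e-9)

  rtri <- ifelse(tt >= 300 & tt <= 500, 10 * (1 - (tt - 300) / 200), 0)
  a <- area_features(rtri, 300, 500)
  expect_equal(a$AUC, 1000, tolerance = 1e-9)
  expect_equal(a$FAL, 300 + 200 - 100 * sqrt(2), tolerance = 1e-6)

  # FAL bisects the area: cumulative area on [T1, FAL] = AUC/2
  half_left <- area_features(rtri, 300, a$FAL)
  expect_equal(half_left$AUC, a$AUC / 2, tolerance = 1e-6)

  neg <- area_features(-tri, 300, 500)
  expect_false(neg$valid)
  expect_true(is.na(neg$FAL))
})

test_that("derived intervals are exact subtractions with enforced ordering", {
  iv <- derived_intervals(247.21, 484.75, 390.88)
  expect_equal(iv$T2T1, 237.54)
  expect_equal(iv$FALT1, 143.67)
  expect_equal(iv$T2FAL, 93.87)
  expect_equal(iv$T2T1, iv$FALT1 + iv$T2FAL)
  expect_error(derived_intervals(400, 400, 400), "ordering")
  withr::with_seed(6, {
    for (i in 1:20) {
      x <- sort(runif(3, 200, 600))
      iv <- derived_intervals(x[1], x[3], x[2])
      expect_equal(iv$T2T1, x[3] - x[1])
      expect_equal(iv$FALT1, x[2] - x[1])
      expect_equal(iv$T2FAL, x[3] - x[2])
    }
  })
})

test_that("shift equivariance: delaying the component shifts times, not areas", {
  tt <- epoch_times()
  measure <- function(center) {
    d <- 6 * exp(-((tt - center)^2) / (2 * 40^2)) - 0.5
    pk <- locate_p300(d)
    zc <- zero_crossings(d, pk$LAT)
    ar <- area_features(d, zc$T1, zc$T2)
    c(LAT = pk$LAT, T1 = zc$T1, T2 = zc$T2, FAL = ar$FAL, AUC = ar$AUC)
  }
  m0 <- measure(400)
  m1 <- measure(420)  # on-grid 20 ms delay
  expect_equal(m1[c("LAT", "T1", "T2", "FAL")],
               m0[c("LAT", "T1", "T2", "FAL")] + 20, tolerance = 1e-9)
  expect_equal(m1[["AUC"]], m0[["AUC"]], tolerance = 1e-9)
  expect_equal(m1[["T2"]] - m1[["T1"]], m0[["T2"]] - m0[["T1"]],
               tolerance = 1e-9)
})

test_that("full extraction flags subjects without a measurable component", {
  p <- noiseless_params(amplitude = 0)
  s <- generate_stimulus_sequence(8, 32, c(1000, 1000), seed = 2)
  sess <- synthesize_session(s, p, seed = 3)
  f <- extract_subject_features(sess, n_target = 8, n_standard = 32)
  expect_false(f$valid)
  expect_true(f$reason %in% c("no_peak", "no_crossings"))

  # a session with no presses at all has no correct target trials
  p2 <- noiseless_params()
  p2$hit_rate <- 0
  sess2 <- synthesize_session(s, p2, seed = 3)
  f2 <- extract_erp_features(sess2)
  expect_false(f2$valid)
  expect_equal(f2$reason, "no_correct_trials")
})

test_that("valid subjects satisfy the ordering and additivity invariants", {
  feats <- measure_subjects("CN", 20, seed0 = 4000)
  ok <- feats[feats$valid, ]
  expect_gt(nrow(ok), 5)
  expect_true(all(ok$T1 < ok$LAT & ok$LAT < ok$T2))
  expect_true(all(ok$T1 < ok$FAL & ok$FAL < ok$T2))
  expect_true(all(ok$LAT >= 300 & ok$LAT <= 600))
  expect_true(all(ok$AUC > 0))
  expect_true(all(abs(ok$T2T1 - (ok$FALT1 + ok$T2FAL)) < 1e-9))
  expect_true(all(abs(ok$T2T1 - (ok$T2 - ok$T1)) < 1e-9))
})
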