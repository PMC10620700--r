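test_that("summary-based and raw-sample pooled t agree with the t.test oracle", {
  withr::with_seed(10, {
    x <- rnorm(30, 1, 2)
    y <- rnorm(20, 0.2, 1.5)
  })
  ours <- students_t(x, y)
  oracle <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(ours$df, unname(oracle$parameter))
  # summary form run on the exact summaries is identical
  from_sum <- students_t_from_summary(mean(x), sd(x), 30, mean(y), sd(y), 20)
  expect_equal(from_sum$t, ours$t, tolerance = 1e-12)

  # swapping groups negates t
  expect_equal(students_t(y, x)$t, -ours$t, tolerance = 1e-12)
})

test_that("degenerate variances give t = 0 or an infinite-t flag", {
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  z <- students_t(c(0, 0), c(1, 1))
  expect_true(z$infinite)
  expect_true(is.infinite(z$t) && z$t < 0)
})

test_that("chi-squared equals the cellwise oracle and the printed sex value", {
  m <- matrix(c(140, 53, 99, 42), 2)  # rows CN/MCI, cols female/male
  res <- chi_squared(m)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res$statistic, sum((m - E)^2 / E), tolerance = 1e-10)
  expect_equal(res$statistic, 0.217, tolerance = 0.02 * 0.217 + 1e-3)
  expect_equal(res$df, 1)

  # proportional rows are independent
  expect_equal(chi_squared(matrix(c(10, 20, 30, 60), 2))$statistic, 0,
               tolerance = 1e-12)
  withr::with_seed(11, {
    for (i in 1:10) {
      t2 <- matrix(rpois(4, 30) + 1, 2)
      E <- outer(rowSums(t2), colSums(t2)) / sum(t2)
      expect_equal(chi_squared(t2)$statistic, sum((t2 - E)^2 / E),
                   tolerance = 1e-10)
    }
  })
  expect_error(chi_squared(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("logistic regression recovers a known odds ratio", {
  withr::with_seed(12, {
    x <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(-1 + log(1.5) * x))
  })
  fit <- fit_logistic(data.frame(y = y, x = x), "y", "x",
                      standardize = FALSE)
  expect_lt(abs(fit$coef - log(1.5)), 3 * fit$se)
  expect_true(fit$ci_low <= fit$odds_ratio && fit$odds_ratio <= fit$ci_high)
  expect_gt(fit$ci_low, 0)
})

test_that("standardized OR equals exp(raw coefficient times raw SD)", {
  withr::with_seed(13, {
    x <- rnorm(800, 50, 9)
    y <- rbinom(800, 1, plogis(-3 + 0.05 * x))
  })
  d <- data.frame(y = y, x = x)
  raw <- fit_logistic(d, "y", "x", standardize = FALSE)
  std <- fit_logistic(d, "y", "x", standardize = TRUE)
  expect_equal(std$odds_ratio, exp(raw$coef * sd(x)), tolerance = 1e-6)
})

test_that("logistic fitting reports degenerate designs and separation", {
  d <- data.frame(y = rep(0:1, 20), x = 1)
  expect_error(fit_logistic(d, "y", "x"), "constant")
  d2 <- data.frame(y = rep(0:1, each = 20),
                   x = c(rnorm(20, -5), rnorm(20, 5)))
  expect_error(suppressWarnings(fit_logistic(d2, "y", "x")), "separation")
  expect_error(fit_logistic(data.frame(y = rep(1, 30), x = rnorm(30)),
                            "y", "x"), "binary")
})

test_that("nested models adjust away a mediated effect", {
  withr::with_seed(14, {
    n <- 1500
    age <- rnorm(n, 73, 6)
    mci <- rbinom(n, 1, plogis(-1 + 0.12 * (age - 73)))
    feature <- age + rnorm(n, 0, 2)  # effect wholly mediated by age
    d <- data.frame(mci = mci, feature = feature, age_years = age,
                    sex_male = rbinom(n, 1, 0.45),
                    education_years = rnorm(n, 10, 4),
                    mmse = rnorm(n, 27, 2))
  })
  fits <- nested_models(d, "feature")
  expect_gt(fits$model1$ci_low, 1)      # unadjusted: strong association
  expect_true(fits$model2$ci_low <= 1)  # age-adjusted: compatible with null
  expect_lt(abs(log(fits$model2$odds_ratio)), abs(log(fits$model1$odds_ratio)))

  # a feature independent of everything: all three ORs near 1
  withr::with_seed(15, d$feature <- rnorm(nrow(d)))
  fits <- nested_models(d, "feature")
  for (f in fits) {
    expect_true(f$ci_low <= 1 && 1 <= f$ci_high)
  }

  # a feature built from MMSE attenuates from model 2 to model 3
  withr::with_seed(16, {
    d$mmse <- 27 - 1.5 * d$mci + rnorm(nrow(d), 0, 1.5)
    d$feature <- -d$mmse + rnorm(nrow(d), 0, 1)
  })
  fits <- nested_models(d, "feature")
  expect_lt(abs(log(fits$model3$odds_ratio)),
            abs(log(fits$model2$odds_ratio)))
})

test_that("partial correlation handles identity, perfect partialling, symmetry", {
  withr::with_seed(17, x <- rnorm(50))
  expect_equal(partial_correlation(x, x)$r, 1)

  withr::with_seed(18, {
    z <- rnorm(60)
    x <- rnorm(60)
  })
  pc <- partial_correlation(x, z, data.frame(z = z))
  expect_lt(abs(pc$r), 1e-9)

  withr::with_seed(19, {
    covs <- data.frame(a = rnorm(60), b = rnorm(60))
    x <- covs$a + rnorm(60)
    y <- covs$a - rnorm(60)
  })
  expect_equal(partial_correlation(x, y, covs)$r,
               partial_correlation(y, x, covs)$r, tolerance = 1e-12)
  # affine transformations of covariates do not change r
  covs2 <- data.frame(a = 3 * covs$a - 7, b = -0.5 * covs$b + 2)
  expect_equal(partial_correlation(x, y, covs2)$r,
               partial_correlation(x, y, covs)$r, tolerance = 1e-10)
  expect_error(partial_correlation(x, y, cbind(covs, a2 = covs$a)), "rank")
})

test_that("partial correlation matches the inverse-correlation-matrix formula", {
  withr::with_seed(20, {
    z1 <- rnorm(80); z2 <- rnorm(80)
    x <- 0.6 * z1 + rnorm(80)
    y <- 0.4 * z1 - 0.3 * z2 + 0.5 * x + rnorm(80)
  })
  pc <- partial_correlation(x, y, data.frame(z1 = z1, z2 = z2))
  P <- solve(cor(cbind(x, y, z1, z2)))
  oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(pc$r, oracle, tolerance = 1e-10)
})

test_that("comparison tables carry the full reference layout", {
  b <- generate_cohort(40, 40, seed = 21, keep_sessions = FALSE)
  subj <- b$subjects
  # attach synthetic feature columns so table construction is exercised
  withr::with_seed(22, {
    for (v in c(erp_feature_names(), behavioral_feature_names())) {
      subj[[v]] <- rnorm(nrow(subj)) + 0.3 * (subj$group == "MCI")
    }
  })
  subj$mci <- as.integer(subj$group == "MCI")
  tabs <- build_comparison_tables(subj)
  expect_equal(nrow(tabs$features), 15)
  expect_equal(nrow(tabs$logistic), 45)
  expect_equal(sort(unique(tabs$logistic$model)), 1:3)
  expect_equal(dim(tabs$correlations$CN$adjusted$r), c(15, 6))
  expect_true(all(abs(tabs$correlations$MCI$raw$r) <= 1))
  sex <- attr(tabs$demographics, "sex")
  expect_equal(sum(sex$table), 80)
  expect_error(build_comparison_tables(subj[subj$group == "CN", ]), "report")
})

test_that("significance stars follow the reporting convention", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.03, 0.05, 0.2)),
               c("***", "**", "*", "*", "ns"))
})
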