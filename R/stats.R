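# Group-comparison statistics: pooled-variance t (from raw data or printed
# summaries), Pearson chi-squared, nested logistic models, partial
# correlations. Sign convention throughout: group1 = CN, group2 = MCI,
# t = (CN - MCI) / SE, so a negative t means the MCI mean is larger.

#' Student's pooled-variance t-test from group summaries
#'
#' Recomputes the two-sample pooled t exactly as printable from a summary
#' table: `t = (mean1 - mean2) / (sp * sqrt(1/n1 + 1/n2))` with
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, `df = n1 + n2 - 2`,
#' two-sided p. Zero pooled variance gives `t = 0` for equal means and an
#' infinite-t flag otherwise.
#'
#' @param mean1,sd1,n1 First group (CN by convention).
#' @param mean2,sd2,n2 Second group (MCI).
#' @return List of class `t_test_result`: `t`, `df`, `p`, `infinite`,
#'   `mean1`, `sd1`, `n1`, `mean2`, `sd2`, `n2`.
#' @export
students_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    tval <- if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2)
  } else {
    tval <- (mean1 - mean2) / se
  }
  structure(list(t = tval, df = df,
                 p = if (is.finite(tval)) 2 * stats::pt(-abs(tval), df) else 0,
                 infinite = !is.finite(tval),
                 mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2),
            class = "t_test_result")
}

#' Student's pooled-variance t-test from raw samples
#'
#' Computes each group's mean and sample SD and delegates to
#' [students_t_from_summary()].
#'
#' @param x,y Numeric vectors (group1 = CN, group2 = MCI), each of length >= 2.
#' @return A `t_test_result`, see [students_t_from_summary()].
#' @export
students_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  students_t_from_summary(mean(x), stats::sd(x), length(x),
                          mean(y), stats::sd(y), length(y))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction (df = 1).
#'
#' @param contingency 2x2 matrix of nonnegative counts with positive margins.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_squared <- function(contingency) {
  m <- as.matrix(contingency)
  stopifnot(all(dim(m) == c(2, 2)), all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-squared undefined: a table margin is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Logistic regression of MCI status on one predictor
#'
#' Maximum-likelihood fit via `stats::glm` (binomial logit, log-likelihood
#' convergence tolerance 1e-8, at most 100 iterations). By default the
#' predictor is standardized to zero mean / unit SD over the analysis sample
#' before fitting, so the odds ratio is per SD of the predictor; covariates
#' enter untransformed. Wald 95% CI and p for the predictor.
#'
#' @param data Data frame containing all variables.
#' @param outcome Name of the binary outcome column (0/1, 1 = MCI).
#' @param predictor Name of the predictor column.
#' @param covariates Character vector of covariate column names.
#' @param standardize Z-score the predictor before fitting.
#' @param conf_level Wald confidence level.
#' @return List of class `logistic_result`: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `coef`, `se`, `predictor`, `covariates`, `n`, `standardized`.
#' @export
fit_logistic <- function(data, outcome, predictor, covariates = character(),
                         standardize = TRUE, conf_level = 0.95) {
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) != 2) {
    stop("outcome must be binary with both classes present")
  }
  x <- data[[predictor]]
  if (standardize) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("rank error: predictor ", predictor, " is constant")
    }
    x <- (x - mean(x)) / s
  }
  df <- data.frame(.y = y, .x = x)
  for (cv in covariates) df[[cv]] <- data[[cv]]
  fml <- stats::as.formula(paste(".y ~ .x",
                                 paste(c("", covariates), collapse = " + ")))
  # separation is detected and reported explicitly below; glm's own warning
  # about fitted probabilities 0/1 is redundant with that check
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged) {
    stop("logistic regression did not converge for predictor ", predictor)
  }
  if (anyNA(stats::coef(fit))) {
    stop("rank error: design matrix is rank deficient for predictor ",
         predictor)
  }
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8) || any(mu > 1 - 1e-8)) {
    stop("perfect (or quasi-perfect) separation detected for predictor ",
         predictor)
  }
  sm <- summary(fit)$coefficients
  b <- sm[".x", "Estimate"]
  se <- sm[".x", "Std. Error"]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(odds_ratio = exp(b), ci_low = exp(b - z * se),
                 ci_high = exp(b + z * se),
                 p_value = sm[".x", "Pr(>|z|)"],
                 coef = b, se = se, predictor = predictor,
                 covariates = covariates, n = nrow(df),
                 standardized = standardize),
            class = "logistic_result")
}

#' The three nested logistic models for one feature
#'
#' Model 1: feature only. Model 2: feature + age, sex, years of education.
#' Model 3: Model 2 + MMSE. Sex is coded female = 0 / male = 1 and the
#' outcome CN = 0 / MCI = 1.
#'
#' @param data Analysis table with `mci` (0/1), the feature column and the
#'   covariate columns.
#' @param feature Feature column name.
#' @param demographics Covariates of Model 2.
#' @param extra Additional covariate of Model 3.
#' @param standardize Passed to [fit_logistic()].
#' @return Named list of three `logistic_result`s (`model1`..`model3`).
#' @export
nested_models <- function(data, feature,
                          demographics = c("age_years", "sex_male",
                                           "education_years"),
                          extra = "mmse", standardize = TRUE) {
  list(model1 = fit_logistic(data, "mci", feature, character(), standardize),
       model2 = fit_logistic(data, "mci", feature, demographics, standardize),
       model3 = fit_logistic(data, "mci", feature, c(demographics, extra),
                             standardize))
}

#' Pearson partial correlation
#'
#' Residualizes `x` and `y` on the covariates (plus intercept) by least
#' squares and correlates the residuals; p-value from
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` with `k` covariates on
#' `n - 2 - k` degrees of freedom. With no covariates this is the plain
#' Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix / data frame of covariates (or `NULL`).
#' @return List of class `partial_cor_result`: `r`, `p`, `df`, `n`, `k`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0 || length(covariates) == 0) {
    k <- 0L
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    z <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(z) == n)
    k <- ncol(z)
    if (n <= k + 2) stop("need n > covariate count + 2")
    zz <- cbind(1, z)
    if (qr(zz)$rank < ncol(zz)) stop("rank error: collinear covariates")
    rx <- stats::lm.fit(zz, x)$residuals
    ry <- stats::lm.fit(zz, y)$residuals
  }
  ssx <- sum(rx^2)
  ssy <- sum(ry^2)
  # a variable fully explained by the covariates has (numerically) zero
  # residual variance: its partial correlation with anything is zero
  if (ssx <= 1e-20 * sum((x - mean(x))^2) ||
      ssy <= 1e-20 * sum((y - mean(y))^2)) {
    r <- 0
  } else {
    r <- sum(rx * ry) / sqrt(ssx * ssy)
  }
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df,
                 n = n, k = k),
            class = "partial_cor_result")
}
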