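# Report-table construction: the group-comparison tables, the nested
# logistic-model table and the per-group correlation matrices.

#' Feature name sets
#'
#' Column order follows the reference report layout: the nine difference-wave
#' measures, then the six behavioral measures.
#' @name feature_sets
#' @export
erp_feature_names <- function() {
  c("FAL", "AUC", "AMP", "LAT", "T1", "T2", "FALT1", "T2FAL", "T2T1")
}

#' @rdname feature_sets
#' @export
behavioral_feature_names <- function() {
  c("NI", "ER", "ACC", "WER", "RT", "RTSD")
}

#' @rdname feature_sets
#' @export
neuropsych_names <- function() {
  c("mmse", "snsb_attention", "snsb_language", "snsb_visuospatial",
    "snsb_memory", "snsb_frontal")
}

#' Significance stars
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p <= 0.05,
#' `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of codes.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p <= 0.05, "*", "ns")))
}

t_row <- function(variable, x_cn, x_mci) {
  tt <- students_t(x_cn, x_mci)
  data.frame(variable = variable,
             cn_mean = tt$mean1, cn_sd = tt$sd1,
             mci_mean = tt$mean2, mci_sd = tt$sd2,
             t = tt$t, df = tt$df, p = tt$p, stars = p_stars(tt$p))
}

#' Build the full set of group-comparison report tables
#'
#' From a cohort analysis table (one row per included subject; column `group`
#' plus demographics, neuropsychological scores and the 15 features) builds:
#' `demographics` (mean (SD) per group with pooled t, chi-squared for sex),
#' `features` (the 15 feature rows with pooled t), `logistic` (odds ratio,
#' Wald 95% CI and p for the three nested models of every feature, predictors
#' z-scored by default) and `correlations` (per group, features x
#' neuropsychological scores, both raw Pearson and partial correlations
#' adjusted for age, sex and years of education). Significance uses a single
#' alpha (default 0.05) with no multiplicity correction and the star codes of
#' [p_stars()].
#'
#' @param cohort Analysis data frame.
#' @param standardize Z-score logistic predictors (per-SD odds ratios).
#' @param alpha Significance level recorded in the output.
#' @return List of class `comparison_tables` with elements `demographics`,
#'   `features`, `logistic`, `correlations`, `alpha`, `n_cn`, `n_mci`.
#' @export
build_comparison_tables <- function(cohort, standardize = TRUE, alpha = 0.05) {
  cn <- cohort[cohort$group == "CN", , drop = FALSE]
  mci <- cohort[cohort$group == "MCI", , drop = FALSE]
  if (nrow(cn) < 2 || nrow(mci) < 2) {
    stop("report error: need at least 2 subjects per group, got ",
         nrow(cn), " CN and ", nrow(mci), " MCI")
  }

  demo_vars <- c(age_years = "Age", education_years = "EDUYR", mmse = "MMSE",
                 snsb_attention = "Attention", snsb_language = "Language",
                 snsb_visuospatial = "Visuospatial", snsb_memory = "Memory",
                 snsb_frontal = "Frontal")
  demographics <- do.call(rbind, lapply(names(demo_vars), function(v) {
    t_row(demo_vars[[v]], cn[[v]], mci[[v]])
  }))
  sex_tab <- rbind(CN = table(factor(cn$sex, c("female", "male"))),
                   MCI = table(factor(mci$sex, c("female", "male"))))
  sex_chi <- chi_squared(sex_tab)
  attr(demographics, "sex") <- list(table = sex_tab,
                                    statistic = sex_chi$statistic,
                                    p = sex_chi$p)

  feats <- c(erp_feature_names(), behavioral_feature_names())
  features <- do.call(rbind, lapply(feats, function(v) {
    t_row(v, cn[[v]], mci[[v]])
  }))

  logistic <- do.call(rbind, lapply(feats, function(v) {
    fits <- tryCatch(nested_models(cohort, v, standardize = standardize),
                     error = function(e) e)
    if (inherits(fits, "error")) {
      # a degenerate fit (separation, rank deficiency) voids the feature's
      # rows but not the rest of the table
      return(data.frame(variable = v, model = 1:3, odds_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        stars = NA_character_,
                        note = conditionMessage(fits)))
    }
    do.call(rbind, lapply(1:3, function(m) {
      f <- fits[[m]]
      data.frame(variable = v, model = m, odds_ratio = f$odds_ratio,
                 ci_low = f$ci_low, ci_high = f$ci_high, p = f$p_value,
                 stars = p_stars(f$p_value), note = "")
    }))
  }))

  np <- neuropsych_names()
  cor_block <- function(g, adjusted) {
    covs <- if (adjusted) {
      cv <- g[, c("age_years", "sex_male", "education_years")]
      # a constant covariate (possible in degenerate simulated cohorts)
      # carries no adjustment and would only break the residualization
      cv <- cv[, vapply(cv, function(x) stats::sd(x) > 0, logical(1)),
               drop = FALSE]
      if (ncol(cv) == 0) NULL else cv
    } else {
      NULL
    }
    r <- matrix(NA_real_, length(feats), length(np),
                dimnames = list(feats, np))
    p <- r
    for (f in feats) {
      for (v in np) {
        pc <- partial_correlation(g[[f]], g[[v]], covs)
        r[f, v] <- pc$r
        p[f, v] <- pc$p
      }
    }
    list(r = r, p = p)
  }
  correlations <- list(
    CN = list(raw = cor_block(cn, FALSE), adjusted = cor_block(cn, TRUE)),
    MCI = list(raw = cor_block(mci, FALSE), adjusted = cor_block(mci, TRUE)))

  structure(list(demographics = demographics, features = features,
                 logistic = logistic, correlations = correlations,
                 alpha = alpha, n_cn = nrow(cn), n_mci = nrow(mci)),
            class = "comparison_tables")
}
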