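# End-to-end pipeline: simulate -> measure -> exclude -> test -> report.

#' Measure one subject's ERP and behavioral features
#'
#' @param session A `session_recording`.
#' @param erp ERP measurement options, see [erp_options()].
#' @param n_target,n_standard Stimulus counts of the session.
#' @return One-row data frame joining the ERP and behavioral features.
#' @export
extract_subject_features <- function(session, erp = erp_options(),
                                     n_target = sum(session$stimuli$kind == "target"),
                                     n_standard = sum(session$stimuli$kind == "standard")) {
  ef <- extract_erp_features(session, erp)
  trials <- attribute_responses(session$stimuli, session$responses,
                                erp$response_window_ms)
  bf <- compute_behavioral(trials, n_target, n_standard)
  bf$n_stray_presses <- attr(trials, "n_stray_presses")
  cbind(ef, bf)
}

#' Build the cohort analysis table with an exclusion ledger
#'
#' Joins subject records to features and applies the inclusion gates in
#' order: subjects with no target responses, then extreme-error performers
#' (`ER` above `extreme_error_ratio`), then subjects without a discernible
#' P300 component (no positive peak, missing zero crossings, or non-positive
#' area). Exclusion accounting always satisfies
#' `n_generated = n_included + sum(ledger counts)`.
#'
#' @param subjects Subject data frame (from a `cohort_bundle`).
#' @param features Feature data frame, one row per subject
#'   (from [extract_subject_features()]).
#' @param extreme_error_ratio ER threshold for the extreme-error gate.
#' @return List with `table` (included subjects only, `mci` indicator added),
#'   `ledger` (named counts), `exclusions` (subject_id -> category).
#' @export
build_cohort_table <- function(subjects, features, extreme_error_ratio = 1) {
  stopifnot(identical(subjects$subject_id, features$subject_id))
  merged <- cbind(subjects,
                  features[, setdiff(names(features), "subject_id")])
  category <- rep(NA_character_, nrow(merged))
  category[!merged$behavioral_valid] <- "no_target_responses"
  extreme <- is.na(category) & !is.na(merged$ER) &
    merged$ER > extreme_error_ratio
  category[extreme] <- "extreme_errors"
  category[is.na(category) & !merged$valid] <- "no_discernible_peak"
  ledger <- c(no_target_responses = sum(category == "no_target_responses",
                                        na.rm = TRUE),
              extreme_errors = sum(category == "extreme_errors", na.rm = TRUE),
              no_discernible_peak = sum(category == "no_discernible_peak",
                                        na.rm = TRUE))
  included <- merged[is.na(category), , drop = FALSE]
  included$mci <- as.integer(included$group == "MCI")
  stopifnot(nrow(merged) == nrow(included) + sum(ledger))
  list(table = included, ledger = ledger,
       exclusions = data.frame(subject_id = merged$subject_id[!is.na(category)],
                               category = category[!is.na(category)]))
}

#' Run the full pipeline on a configuration
#'
#' Simulates the cohort subject by subject (sessions are regenerated from
#' per-subject seeds and not retained, so memory stays flat), measures the
#' ERP and behavioral features, applies the exclusion gates, and runs the
#' statistical battery. Fully seed-deterministic.
#'
#' @param config A `pipeline_config`.
#' @param progress Print a note every 50 subjects.
#' @return List of class `pipeline_result`: `subjects`, `features`, `cohort`
#'   (included analysis table), `ledger`, `exclusions`, `tables`
#'   (see [build_comparison_tables()]), `config_digest`.
#' @export
run_pipeline <- function(config = pipeline_config(), progress = FALSE) {
  bundle <- generate_cohort(config$n_cn, config$n_mci, config$calibration,
                            seed = config$seed, n_target = config$n_target,
                            n_standard = config$n_standard,
                            isi_range_ms = config$isi_range_ms,
                            keep_sessions = FALSE)
  subjects <- bundle$subjects
  n <- nrow(subjects)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    session <- synthesize_subject_session(
      bundle$params[[i]],
      c(subjects$seed_params[i], subjects$seed_stimuli[i],
        subjects$seed_session[i]),
      subjects$subject_id[i], config$n_target, config$n_standard,
      config$isi_range_ms)
    feats[[i]] <- extract_subject_features(session, config$erp,
                                           config$n_target, config$n_standard)
    if (progress && i %% 50 == 0) {
      message("measured ", i, "/", n, " subjects")
    }
  }
  features <- do.call(rbind, feats)
  ct <- build_cohort_table(subjects, features, config$extreme_error_ratio)
  tables <- build_comparison_tables(ct$table,
                                    standardize = config$standardize_predictors,
                                    alpha = config$alpha)
  structure(list(subjects = subjects, features = features,
                 cohort = ct$table, ledger = ct$ledger,
                 exclusions = ct$exclusions, tables = tables,
                 config_digest = bundle$config_digest),
            class = "pipeline_result")
}

#' Render comparison tables as Markdown and JSON
#'
#' @param tables A `comparison_tables` list.
#' @param path Optional stem; writes `<path>.md` and `<path>.json`.
#' @param ledger Optional exclusion ledger (named counts) to include.
#' @return List with `markdown` (character scalar) and `json` (list ready for
#'   serialization), invisibly when `path` is given.
#' @export
render_report <- function(tables, path = NULL, ledger = NULL) {
  stopifnot(inherits(tables, "comparison_tables"))
  fm <- function(x, d = 2) formatC(x, format = "f", digits = d)
  md <- c(
    "# Group comparison report", "",
    sprintf("Included subjects: %d CN, %d MCI (alpha = %g, significance: %s)",
            tables$n_cn, tables$n_mci, tables$alpha,
            "*** p<0.001, ** p<0.01, * p<=0.05, ns otherwise"), "")
  if (!is.null(ledger)) {
    md <- c(md, "Exclusions: ",
            paste(sprintf("%s = %d", names(ledger), ledger), collapse = ", "),
            "")
  }
  sex <- attr(tables$demographics, "sex")
  md <- c(md, "## Demographics and neuropsychological scores", "",
          "| Variable | CN mean (SD) | MCI mean (SD) | t | p |",
          "|---|---|---|---|---|",
          sprintf("| %s | %s (%s) | %s (%s) | %s | %s %s |",
                  tables$demographics$variable,
                  fm(tables$demographics$cn_mean), fm(tables$demographics$cn_sd),
                  fm(tables$demographics$mci_mean), fm(tables$demographics$mci_sd),
                  fm(tables$demographics$t, 3), format.pval(tables$demographics$p, digits = 3),
                  tables$demographics$stars),
          sprintf("| Sex (chi-squared) |  |  | %s | %s %s |",
                  fm(sex$statistic, 3), format.pval(sex$p, digits = 3),
                  p_stars(sex$p)), "",
          "## ERP and behavioral measures", "",
          "| Variable | CN mean (SD) | MCI mean (SD) | t | p |",
          "|---|---|---|---|---|",
          sprintf("| %s | %s (%s) | %s (%s) | %s | %s %s |",
                  tables$features$variable,
                  fm(tables$features$cn_mean), fm(tables$features$cn_sd),
                  fm(tables$features$mci_mean), fm(tables$features$mci_sd),
                  fm(tables$features$t, 3), format.pval(tables$features$p, digits = 3),
                  tables$features$stars), "",
          "## Logistic models (OR per predictor SD, Wald 95% CI)", "",
          "| Variable | Model | OR (95% CI) | p |",
          "|---|---|---|---|",
          sprintf("| %s | %d | %s (%s, %s) | %s %s |",
                  tables$logistic$variable, tables$logistic$model,
                  fm(tables$logistic$odds_ratio), fm(tables$logistic$ci_low),
                  fm(tables$logistic$ci_high),
                  format.pval(tables$logistic$p, digits = 3),
                  tables$logistic$stars), "")
  json <- list(
    n_cn = tables$n_cn, n_mci = tables$n_mci, alpha = tables$alpha,
    demographics = tables$demographics,
    sex = list(table = as.data.frame.matrix(sex$table),
               statistic = sex$statistic, p = sex$p),
    features = tables$features,
    logistic = tables$logistic,
    correlations = lapply(tables$correlations, function(g) {
      lapply(g, function(kind) list(r = kind$r, p = kind$p))
    }),
    ledger = as.list(ledger))
  out <- list(markdown = paste(md, collapse = "\n"), json = json)
  if (!is.null(path)) {
    writeLines(out$markdown, paste0(path, ".md"))
    jsonlite::write_json(json, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", matrix = "rowmajor")
    return(invisible(out))
  }
  out
}
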