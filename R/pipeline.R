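.aspirin_variables <- function(model) {
  vars <- vapply(model$variables, `[[`, "", "source_column")
  vapply(model$variables, `[[`, "", "name")[vars == "aspirin_use"]
}

.auc_row <- function(model_name, extra, res) {
  if (is.character(res)) {
    cbind(data.frame(model_name = model_name, stringsAsFactors = FALSE),
          extra,
          data.frame(auc = NA_real_, variance = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, n_cases = NA_integer_,
                     n_controls = NA_integer_,
                     note = paste0("undefined: ", res),
                     stringsAsFactors = FALSE))
  } else {
    cbind(data.frame(model_name = model_name, stringsAsFactors = FALSE),
          extra,
          data.frame(auc = res$auc, variance = res$variance,
                     ci_low = res$ci_low, ci_high = res$ci_high,
                     n_cases = res$n_cases, n_controls = res$n_controls,
                     note = "", stringsAsFactors = FALSE))
  }
}

#' Run the full external-validation pipeline
#'
#' Orchestrates the complete analysis for a cohort and a registry of
#' risk-model specifications: cohort exclusions, scoring of every model,
#' overall discrimination for each outcome composite, subgroup
#' discrimination, comparison of every model against the age-threshold
#' comparator by paired DeLong tests, top-fraction screening metrics,
#' decile calibration and recalibration for models publishing absolute
#' risk, a Cox concordance sensitivity analysis, and an
#' aspirin-term-removal sensitivity analysis for models containing an
#' aspirin variable. Sex-restricted models are evaluated in both sexes
#' (with a note), mirroring external-validation practice.
#'
#' The run is deterministic given the cohort and configuration: no
#' random numbers are consumed.
#'
#' @param cohort A schema-conforming cohort with follow-up fields, or a
#'   path readable by [read_cohort()].
#' @param models A named list of `risk_model` objects (default: the
#'   shipped registry) or a directory path for [load_model_registry()].
#' @param outcomes Outcome composites to analyse (default all five).
#' @param subgroups Subgroup schemes among `"sex"`, `"urbanicity"`,
#'   `"age"` (applied to the primary CRC outcome).
#' @param top_fractions Flagged fractions for screening metrics.
#' @param calibration_groups Number of risk groups for calibration.
#' @param comparator_cutoff Age cutoff (years) of the comparator model.
#' @param aspirin_policy `"impute_nonuse"` (default: missing aspirin use
#'   is imputed as non-use, per the spec files' missing policy) or
#'   `"drop_term"` (the aspirin term is removed from every model
#'   containing one).
#' @param observed_estimator Observed-risk estimator for calibration.
#' @return An object of class `validation_report`.
#' @export
run_validation <- function(cohort, models = NULL,
                           outcomes = outcome_sets(),
                           subgroups = c("sex", "urbanicity", "age"),
                           top_fractions = c(0.10, 0.25),
                           calibration_groups = 10L,
                           comparator_cutoff = 56,
                           aspirin_policy = c("impute_nonuse", "drop_term"),
                           observed_estimator = c("km", "crude")) {
  aspirin_policy <- match.arg(aspirin_policy)
  observed_estimator <- match.arg(observed_estimator)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.null(models)) models <- load_model_registry()
  if (is.character(models)) models <- load_model_registry(models)
  stopifnot(comparator_cutoff >= 30, comparator_cutoff <= 79,
            all(top_fractions > 0 & top_fractions < 1))
  outcomes <- match.arg(outcomes, outcome_sets(), several.ok = TRUE)

  excl <- apply_exclusions(cohort)
  cohort <- excl$cohort

  fu <- lapply(outcomes, function(os) build_followup(cohort, os))
  names(fu) <- outcomes
  primary <- if ("CRC" %in% outcomes) "CRC" else outcomes[[1L]]
  labels_primary <- fu[[primary]]$event

  # score every model; a failing model is marked undefined, not fatal
  scores <- list()
  score_notes <- character(0)
  for (nm in names(models)) {
    m <- models[[nm]]
    drop_vars <- if (aspirin_policy == "drop_term") .aspirin_variables(m)
                 else character(0)
    res <- tryCatch(
      suppressWarnings(score_cohort(m, cohort, drop_variables = drop_vars,
                                    enforce_sex = FALSE)),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      scores[nm] <- list(NULL)
      score_notes[nm] <- res
    } else {
      scores[[nm]] <- res
      score_notes[nm] <- if (m$applicable_sex == "both") "" else
        paste0("developed in ", m$applicable_sex,
               "s only; evaluated in both sexes")
    }
  }

  # overall discrimination, one row per model x outcome composite
  auc_overall <- do.call(rbind, lapply(names(models), function(nm) {
    do.call(rbind, lapply(outcomes, function(os) {
      extra <- data.frame(outcome_set = os, stringsAsFactors = FALSE)
      if (is.null(scores[[nm]])) return(.auc_row(nm, extra, score_notes[nm]))
      res <- tryCatch(empirical_auc(scores[[nm]]$score, fu[[os]]$event,
                                    model_name = nm),
                      error = function(e) conditionMessage(e))
      .auc_row(nm, extra, res)
    }))
  }))

  # subgroup discrimination on the primary outcome
  auc_subgroups <- do.call(rbind, lapply(names(models), function(nm) {
    do.call(rbind, lapply(subgroups, function(gr) {
      if (is.null(scores[[nm]])) {
        strata <- switch(gr, sex = c("male", "female"),
                         urbanicity = c("urban", "rural"),
                         age = paste0(c("age_lt_", "age_ge_"),
                                      comparator_cutoff))
        return(do.call(rbind, lapply(strata, function(st)
          data.frame(model_name = nm, grouping = gr, stratum = st,
                     auc = NA_real_, variance = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, n_cases = NA_integer_,
                     n_controls = NA_integer_,
                     note = paste0("undefined: ", score_notes[nm]),
                     stringsAsFactors = FALSE))))
      }
      subgroup_discrimination(cohort, scores[[nm]]$score, labels_primary,
                              grouping = gr, age_cutoff = comparator_cutoff,
                              model_name = nm)
    }))
  }))

  # age-threshold comparator and paired DeLong contrasts
  age_score <- as.numeric(cohort$age >= comparator_cutoff)
  age_auc <- empirical_auc(age_score, labels_primary,
                           model_name = "age_threshold")
  delong_vs_age <- do.call(rbind, lapply(names(models), function(nm) {
    if (is.null(scores[[nm]])) {
      return(data.frame(model_name = nm, auc_model = NA_real_,
                        auc_age = age_auc$auc, auc_difference = NA_real_,
                        z = NA_real_, p_two_sided = NA_real_,
                        p_bonferroni = NA_real_,
                        note = paste0("undefined: ", score_notes[nm]),
                        stringsAsFactors = FALSE))
    }
    ct <- delong_paired_test(scores[[nm]]$score, age_score, labels_primary,
                             model_a = nm, model_b = "age_threshold")
    data.frame(model_name = nm, auc_model = ct$auc_a, auc_age = ct$auc_b,
               auc_difference = ct$auc_difference, z = ct$z,
               p_two_sided = ct$p_two_sided,
               p_bonferroni = min(1, ct$p_two_sided * length(models)),
               note = "", stringsAsFactors = FALSE)
  }))

  # top-fraction screening metrics on the primary outcome
  topk <- do.call(rbind, lapply(names(models), function(nm) {
    do.call(rbind, lapply(top_fractions, function(f) {
      if (is.null(scores[[nm]])) {
        return(data.frame(model_name = nm, fraction = f,
                          n_flagged = NA_integer_, threshold = NA_real_,
                          sensitivity = NA_real_, specificity = NA_real_,
                          ppv = NA_real_, npv = NA_real_,
                          note = paste0("undefined: ", score_notes[nm]),
                          stringsAsFactors = FALSE))
      }
      tk <- topk_metrics(scores[[nm]]$score, labels_primary, f,
                         ids = cohort$id, model_name = nm)
      data.frame(model_name = nm, fraction = f, n_flagged = tk$n_flagged,
                 threshold = tk$threshold, sensitivity = tk$sensitivity,
                 specificity = tk$specificity, ppv = tk$ppv, npv = tk$npv,
                 note = "", stringsAsFactors = FALSE)
    }))
  }))

  # calibration for models publishing absolute risk
  calib <- list()
  calib_notes <- character(0)
  for (nm in names(models)) {
    if (is.null(scores[[nm]]) || !provides_absolute_risk(models[[nm]])) next
    res <- tryCatch(
      calibrate_model(scores[[nm]]$risk_10y, fu[[primary]],
                      n_groups = calibration_groups,
                      estimator = observed_estimator, model_name = nm,
                      by = scores[[nm]]$score),
      error = function(e) conditionMessage(e))
    if (is.character(res)) calib_notes[nm] <- res else calib[[nm]] <- res
  }

  # Cox concordance sensitivity analysis
  cstat <- do.call(rbind, lapply(names(models), function(nm) {
    if (is.null(scores[[nm]])) {
      return(data.frame(model_name = nm, cstat = NA_real_,
                        note = paste0("undefined: ", score_notes[nm]),
                        stringsAsFactors = FALSE))
    }
    data.frame(model_name = nm,
               cstat = concordance_cox(fu[[primary]]$time_years,
                                       fu[[primary]]$event,
                                       scores[[nm]]$score),
               note = "", stringsAsFactors = FALSE)
  }))

  aspirin <- aspirin_sensitivity(cohort, models, fu[[primary]])

  report <- list(
    models = names(models),
    outcomes = outcomes, subgroups = subgroups,
    top_fractions = top_fractions,
    comparator_cutoff = comparator_cutoff,
    aspirin_policy = aspirin_policy,
    observed_estimator = observed_estimator,
    n = nrow(cohort),
    exclusion_log = excl$log,
    score_notes = score_notes,
    auc_overall = auc_overall,
    auc_subgroups = auc_subgroups,
    age_auc = age_auc,
    delong_vs_age = delong_vs_age,
    topk = topk,
    calibration = calib,
    calibration_notes = calib_notes,
    cstat = cstat,
    aspirin = aspirin,
    package_version = as.character(utils::packageVersion("crcval"))
  )
  class(report) <- "validation_report"
  report
}

#' Aspirin-term sensitivity analysis
#'
#' For every model containing an aspirin variable, compares the model's
#' discrimination with the aspirin term included (missing use imputed as
#' non-use) against the same model with the term removed, on identical
#' records, with a paired DeLong contrast. Motivated by cohorts where
#' aspirin use is recorded only in a medical-history subgroup.
#'
#' @param cohort A cohort data frame (post-exclusion).
#' @param models A named list of `risk_model` objects.
#' @param followup Follow-up table for the outcome composite (from
#'   [build_followup()]).
#' @return A data frame with one row per aspirin-containing model:
#'   `model_name`, `auc_with`, `auc_without`, `auc_difference`, `z`,
#'   `p_two_sided`; or `NULL` when no model contains an aspirin term.
#' @export
aspirin_sensitivity <- function(cohort, models, followup) {
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    asp <- .aspirin_variables(m)
    if (length(asp) == 0L) return(NULL)
    s_with <- tryCatch(
      suppressWarnings(score_cohort(m, cohort, enforce_sex = FALSE)$score),
      error = function(e) NULL)
    if (is.null(s_with)) return(NULL)
    s_without <- suppressWarnings(
      score_cohort(m, cohort, drop_variables = asp,
                   enforce_sex = FALSE)$score)
    ct <- delong_paired_test(s_with, s_without, followup$event,
                             model_a = paste0(nm, "+aspirin"),
                             model_b = nm)
    data.frame(model_name = nm, auc_with = ct$auc_a,
               auc_without = ct$auc_b, auc_difference = ct$auc_difference,
               z = ct$z, p_two_sided = ct$p_two_sided,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, FALSE)]
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  participants (post-exclusion):", x$n, "\n")
  cat("  models:", paste(x$models, collapse = ", "), "\n")
  cat("  outcome composites:", paste(x$outcomes, collapse = ", "), "\n")
  cat("  subgroup schemes:", paste(x$subgroups, collapse = ", "),
      "+ outcome site\n")
  cat(sprintf("  age comparator (>= %s y): AUC %.3f\n", x$comparator_cutoff,
              x$age_auc$auc))
  cat("  calibration tables:", length(x$calibration), "model(s)\n")
  invisible(x)
}

#' @export
summary.validation_report <- function(object, ...) {
  cat("External validation of", length(object$models),
      "risk models on", object$n, "participants\n\n")
  cat("Overall AUC (primary outcome):\n")
  ov <- object$auc_overall
  print(ov[ov$outcome_set == object$outcomes[[1L]],
           c("model_name", "auc", "ci_low", "ci_high", "note")],
        row.names = FALSE, digits = 3)
  cat(sprintf("\nAge-threshold comparator AUC: %.3f [%.3f, %.3f]\n",
              object$age_auc$auc, object$age_auc$ci_low,
              object$age_auc$ci_high))
  cat("\nDeLong contrasts vs age comparator:\n")
  print(object$delong_vs_age[, c("model_name", "auc_difference", "z",
                                 "p_two_sided")],
        row.names = FALSE, digits = 3)
  cat("\nTop-fraction screening metrics:\n")
  print(object$topk[, c("model_name", "fraction", "sensitivity",
                        "specificity", "ppv", "npv")],
        row.names = FALSE, digits = 3)
  if (length(object$calibration) > 0L) {
    cat("\nCalibration slopes/intercepts:\n")
    for (cf in object$calibration) {
      cat(sprintf("  %-14s slope %6.3f  intercept %9.6f\n",
                  cf$model_name, cf$slope, cf$intercept))
    }
  }
  if (!is.null(object$aspirin)) {
    cat("\nAspirin-term sensitivity:\n")
    print(object$aspirin, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

.write_table <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
}

#' Write a validation report as delimited tables
#'
#' Emits one CSV per result block (`auc_overall`, `auc_subgroups`,
#' `delong_vs_age`, `topk`, `cstat`, `sensitivity_aspirin`,
#' `exclusions`, one `calibration_<model>` per calibrated model) plus a
#' `manifest.txt` recording the configuration. Output is deterministic:
#' re-running the same report writes byte-identical files.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_table(report$auc_overall, file.path(dir, "auc_overall.csv"))
  .write_table(report$auc_subgroups, file.path(dir, "auc_subgroups.csv"))
  .write_table(report$delong_vs_age, file.path(dir, "delong_vs_age.csv"))
  .write_table(report$topk, file.path(dir, "topk.csv"))
  .write_table(report$cstat, file.path(dir, "cstat.csv"))
  .write_table(report$exclusion_log, file.path(dir, "exclusions.csv"))
  if (!is.null(report$aspirin)) {
    .write_table(report$aspirin, file.path(dir, "sensitivity_aspirin.csv"))
  }
  for (cf in report$calibration) {
    .write_table(cbind(data.frame(model_name = cf$model_name,
                                  slope = cf$slope,
                                  intercept = cf$intercept),
                       cf$table),
                 file.path(dir, paste0("calibration_", cf$model_name,
                                       ".csv")))
  }
  manifest <- c(
    paste0("crcval version: ", report$package_version),
    paste0("participants: ", report$n),
    paste0("models: ", paste(report$models, collapse = ", ")),
    paste0("outcomes: ", paste(report$outcomes, collapse = ", ")),
    paste0("subgroups: ", paste(report$subgroups, collapse = ", ")),
    paste0("top fractions: ", paste(report$top_fractions, collapse = ", ")),
    paste0("comparator cutoff: ", report$comparator_cutoff),
    paste0("aspirin policy: ", report$aspirin_policy),
    paste0("observed-risk estimator: ", report$observed_estimator),
    paste0("calibrated models: ",
           paste(names(report$calibration), collapse = ", "))
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
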