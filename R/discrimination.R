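# DeLong structural components via midranks.
# For case i: V10_i = P-hat(score_i > random control) with ties half-credit,
# computed as (pooled midrank - within-case midrank) / n_controls; the
# control components V01 are symmetric. AUC = mean(V10) = mean(V01).
.delong_components <- function(scores, cases) {
  x <- scores[cases]
  y <- scores[!cases]
  n1 <- length(x)
  n0 <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_x) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_y) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10), n1 = n1, n0 = n0)
}

.check_two_class <- function(labels, scores) {
  if (!all(is.finite(scores))) {
    stop("degenerate-input error: scores must be finite", call. = FALSE)
  }
  labels <- as.logical(labels)
  if (anyNA(labels)) {
    stop("degenerate-input error: labels must be non-missing", call. = FALSE)
  }
  if (sum(labels) < 1L || sum(!labels) < 1L) {
    stop("degenerate-input error: need at least one case and one control",
         call. = FALSE)
  }
  labels
}

#' Empirical AUC with DeLong variance
#'
#' The area under the ROC curve computed as the Mann-Whitney statistic
#' (probability a random case outscores a random control, ties scored
#' 0.5), with its variance from the DeLong per-observation structural
#' components and a Wald confidence interval truncated to `[0, 1]`.
#'
#' @param scores Finite numeric marker values.
#' @param labels Logical (or 0/1) case indicators; at least one case and
#'   one control required.
#' @param conf_level Confidence level of the Wald interval.
#' @param model_name Optional label carried into the result.
#' @return An object of class `auc_result`: a list with `model_name`,
#'   `auc`, `variance`, `ci_low`, `ci_high`, `n_cases`, `n_controls`.
#' @export
empirical_auc <- function(scores, labels, conf_level = 0.95,
                          model_name = NA_character_) {
  if (length(scores) != length(labels)) {
    stop("degenerate-input error: scores and labels differ in length",
         call. = FALSE)
  }
  labels <- .check_two_class(labels, scores)
  cmp <- .delong_components(scores, labels)
  v <- stats::var(cmp$v10) / cmp$n1 + stats::var(cmp$v01) / cmp$n0
  if (cmp$n1 == 1L && cmp$n0 == 1L) v <- 0
  if (is.na(v)) v <- 0  # single case or control: that component drops out
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(model_name = model_name, auc = cmp$auc, variance = v,
                 ci_low = max(0, cmp$auc - z * sqrt(v)),
                 ci_high = min(1, cmp$auc + z * sqrt(v)),
                 n_cases = cmp$n1, n_controls = cmp$n0),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f [%.4f, %.4f] (%d cases / %d controls%s)\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls,
              if (is.na(x$model_name)) "" else
                paste0("; model ", x$model_name)))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Tests the difference between the AUCs of two markers measured on the
#' same participants, using the DeLong variance-covariance of the
#' structural components: `z = (AUC_a - AUC_b) / sqrt(var_a + var_b -
#' 2 cov_ab)`, with a two-sided normal p-value.
#'
#' @param scores_a,scores_b Finite numeric scores on identical
#'   participants, in the same order.
#' @param labels Case indicators shared by both markers.
#' @param model_a,model_b Optional labels.
#' @return A list of class `delong_test` with `model_a`, `model_b`,
#'   `auc_a`, `auc_b`, `auc_difference`, `z`, `p_two_sided`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               model_a = "a", model_b = "b") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("degenerate-input error: score vectors must cover identical ",
         "participants", call. = FALSE)
  }
  labels <- .check_two_class(labels, c(scores_a, scores_b))
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  d <- ca$auc - cb$auc
  var_diff <- stats::var(ca$v10 - cb$v10) / ca$n1 +
    stats::var(ca$v01 - cb$v01) / ca$n0
  if (is.na(var_diff)) var_diff <- 0
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      z <- 0
    } else {
      stop("numerical-degeneracy error: zero variance of the AUC ",
           "difference with unequal AUCs", call. = FALSE)
    }
  } else {
    z <- d / sqrt(var_diff)
  }
  structure(list(model_a = model_a, model_b = model_b,
                 auc_a = ca$auc, auc_b = cb$auc, auc_difference = d,
                 z = z, p_two_sided = 2 * stats::pnorm(-abs(z))),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf(
    "DeLong paired test: AUC(%s) %.4f vs AUC(%s) %.4f; diff %+.4f, z %.3f, p %.4g\n",
    x$model_a, x$auc_a, x$model_b, x$auc_b, x$auc_difference, x$z,
    x$p_two_sided))
  invisible(x)
}

#' Age-threshold comparator model
#'
#' The screening-policy comparator: a model whose only input is the
#' indicator `age >= cutoff` (default 56 years, the lower bound of the
#' UK FIT screening age range). For such a binary marker the AUC equals
#' `(sensitivity + specificity) / 2` of the indicator.
#'
#' @param ages Numeric ages in years.
#' @param labels Case indicators.
#' @param cutoff Age threshold in years.
#' @param ... Passed to [empirical_auc()].
#' @return An `auc_result` (model name `age_threshold`).
#' @export
age_threshold_comparator <- function(ages, labels, cutoff = 56, ...) {
  empirical_auc(as.numeric(ages >= cutoff), labels,
                model_name = "age_threshold", ...)
}

#' Harrell's concordance for a risk score against censored event times
#'
#' Concordance over usable pairs: a pair is usable when one member had
#' the event and the other member's follow-up time is strictly longer
#' (an event versus a longer-surviving comparator). The pair is
#' concordant when the event member carries the higher score; score
#' ties are credited 0.5. Pairs tied on time are not usable.
#'
#' Evaluation is exhaustive (vectorised over events), so the estimate
#' equals the all-pairs definition exactly; with rare events this stays
#' fast even for large cohorts.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1/TRUE = event).
#' @param scores Risk scores (higher = higher predicted risk).
#' @return Harrell's C as a number in `[0, 1]`.
#' @export
concordance_cox <- function(times, events, scores) {
  stopifnot(length(times) == length(events),
            length(times) == length(scores))
  if (any(times <= 0)) {
    stop("degenerate-input error: times must be positive", call. = FALSE)
  }
  events <- as.logical(events)
  conc <- 0
  usable <- 0
  for (i in which(events)) {
    later <- times > times[i]
    m <- sum(later)
    if (m == 0L) next
    usable <- usable + m
    conc <- conc + sum(scores[i] > scores[later]) +
      0.5 * sum(scores[i] == scores[later])
  }
  if (usable == 0) {
    stop("degenerate-input error: no usable (comparable) pairs",
         call. = FALSE)
  }
  conc / usable
}

#' Screening metrics for the top risk fraction
#'
#' Flags the `ceiling(fraction * n)` participants with the highest
#' scores (ties broken by stable participant order: score descending,
#' then id ascending) and reports the 2x2-table metrics of that
#' flag against the outcome labels.
#'
#' @param scores Finite numeric scores.
#' @param labels Case indicators.
#' @param fraction Flagged fraction in `(0, 1)`; the validation analyses
#'   use 0.10 and 0.25.
#' @param ids Participant identifiers for deterministic tie-breaking;
#'   defaults to input order.
#' @param model_name Optional label.
#' @return A list of class `topk_metrics`: `model_name`, `fraction`,
#'   `n_flagged`, `threshold` (lowest flagged score), `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
topk_metrics <- function(scores, labels, fraction, ids = seq_along(scores),
                         model_name = NA_character_) {
  stopifnot(fraction > 0, fraction < 1)
  labels <- .check_two_class(labels, scores)
  n <- length(scores)
  k <- as.integer(ceiling(fraction * n))
  ord <- order(-scores, ids)
  flagged <- logical(n)
  flagged[ord[seq_len(k)]] <- TRUE
  tp <- sum(flagged & labels)
  fp <- sum(flagged & !labels)
  fn <- sum(!flagged & labels)
  tn <- sum(!flagged & !labels)
  structure(list(model_name = model_name, fraction = fraction,
                 n_flagged = k, threshold = min(scores[flagged]),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 ppv = tp / (tp + fp), npv = tn / (tn + fn)),
            class = "topk_metrics")
}

#' @export
print.topk_metrics <- function(x, ...) {
  cat(sprintf(
    "Top %.0f%% flagged (n=%d): sens %.3f, spec %.3f, PPV %.4f, NPV %.4f\n",
    100 * x$fraction, x$n_flagged, x$sensitivity, x$specificity, x$ppv,
    x$npv))
  invisible(x)
}

#' Discrimination within cohort subgroups
#'
#' Computes the AUC of a score separately within the strata of a
#' grouping: sex, urban/rural residence, or age below/at-or-above a
#' cutoff (default 56). Strata without both a case and a control are
#' reported as undefined with a reason rather than dropped.
#'
#' @param cohort Cohort data frame aligned with `scores` and `labels`.
#' @param scores Numeric scores.
#' @param labels Case indicators.
#' @param grouping One of `"sex"`, `"urbanicity"`, `"age"`.
#' @param age_cutoff Cutoff for the age grouping, years.
#' @param model_name Optional label.
#' @return A data frame with one row per stratum: `model_name`,
#'   `grouping`, `stratum`, `auc`, `variance`, `ci_low`, `ci_high`,
#'   `n_cases`, `n_controls`, `note`.
#' @export
subgroup_discrimination <- function(cohort, scores, labels,
                                    grouping = c("sex", "urbanicity", "age"),
                                    age_cutoff = 56,
                                    model_name = NA_character_) {
  if (length(grouping) != 1L ||
      !grouping %in% c("sex", "urbanicity", "age")) {
    stop("configuration error: unknown grouping '",
         paste(grouping, collapse = "/"), "'", call. = FALSE)
  }
  strata <- switch(grouping,
    sex = stats::setNames(list(cohort$sex == "male",
                               cohort$sex == "female"),
                          c("male", "female")),
    urbanicity = stats::setNames(list(cohort$urban, !cohort$urban),
                                 c("urban", "rural")),
    age = stats::setNames(
      list(cohort$age < age_cutoff, cohort$age >= age_cutoff),
      c(paste0("age_lt_", age_cutoff), paste0("age_ge_", age_cutoff)))
  )
  rows <- lapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    res <- tryCatch(empirical_auc(scores[idx], labels[idx]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(model_name = model_name, grouping = grouping,
                 stratum = nm, auc = NA_real_, variance = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_cases = sum(labels[idx]),
                 n_controls = sum(!labels[idx]),
                 note = res, stringsAsFactors = FALSE)
    } else {
      data.frame(model_name = model_name, grouping = grouping,
                 stratum = nm, auc = res$auc, variance = res$variance,
                 ci_low = res$ci_low, ci_high = res$ci_high,
                 n_cases = res$n_cases, n_controls = res$n_controls,
                 note = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
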