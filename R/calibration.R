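#' Assign records to quantile groups of predicted risk
#'
#' Groups records by empirical quantiles of their predicted risks
#' (deciles by default). Tied risks are assigned to the lower group, so
#' group sizes differ by at most one only in the untied case.
#'
#' @param risks Numeric predicted risks.
#' @param n_groups Number of quantile groups (default 10).
#' @return Integer vector of group indices in `1..n_groups`.
#' @export
quantile_groups <- function(risks, n_groups = 10L) {
  stopifnot(n_groups >= 2L)
  if (anyNA(risks)) {
    stop("degenerate-input error: risks contain missing values",
         call. = FALSE)
  }
  if (n_groups > length(risks)) {
    stop("configuration error: ", n_groups, " groups requested for only ",
         length(risks), " usable record(s)", call. = FALSE)
  }
  if (length(unique(risks)) == 1L) {
    stop("degenerate-input error: all risks identical, a single effective ",
         "group cannot support quantile calibration", call. = FALSE)
  }
  n <- length(risks)
  r <- rank(risks, ties.method = "min")
  as.integer(ceiling(r * n_groups / n))
}

#' Observed outcome risk of a group over a horizon
#'
#' Default estimator is the Kaplan-Meier complement `1 - S(horizon)`
#' within the group, which accounts for censoring before the horizon;
#' a crude event proportion is available as an alternative (the two
#' coincide when no one is censored early).
#'
#' @param time_years Follow-up times of the group's records.
#' @param event Event indicators.
#' @param horizon Horizon in years (default 10).
#' @param estimator `"km"` or `"crude"`.
#' @return Observed risk as a probability.
#' @export
observed_risk <- function(time_years, event, horizon = 10,
                          estimator = c("km", "crude")) {
  estimator <- match.arg(estimator)
  if (length(time_years) == 0L) {
    stop("degenerate-input error: empty group", call. = FALSE)
  }
  if (estimator == "crude") {
    return(mean(event & time_years <= horizon))
  }
  fit <- survival::survfit(survival::Surv(time_years, as.numeric(event)) ~ 1)
  s <- summary(fit, times = horizon, extend = TRUE)$surv
  1 - s
}

#' Fit the calibration line of observed on expected risk
#'
#' Ordinary least squares of the group-level observed risks on the
#' group-level mean expected risks. Perfect mean calibration gives slope
#' 1, intercept 0.
#'
#' @param expected Per-group mean expected risks (length >= 2).
#' @param observed Per-group observed risks.
#' @return Named numeric vector `c(slope =, intercept =)`.
#' @export
calibration_line <- function(expected, observed) {
  stopifnot(length(expected) == length(observed))
  if (length(expected) < 2L) {
    stop("degenerate-input error: need >= 2 groups", call. = FALSE)
  }
  if (stats::var(expected) == 0) {
    stop("undefined-slope error: zero variance in expected risk",
         call. = FALSE)
  }
  fit <- stats::lm(observed ~ expected)
  c(slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]))
}

#' Affine recalibration of predicted risks
#'
#' Applies `slope * risk + intercept` and clamps the result to `[0, 1]`;
#' the number of clamped values is attached as attribute `n_clamped`.
#'
#' @param risk_values Predicted risks.
#' @param slope,intercept Calibration-line coefficients from
#'   [calibration_line()].
#' @return Recalibrated risks with attribute `n_clamped`.
#' @export
recalibrate <- function(risk_values, slope, intercept) {
  r <- slope * risk_values + intercept
  clamped <- sum(r < 0 | r > 1, na.rm = TRUE)
  r <- pmin(pmax(r, 0), 1)
  attr(r, "n_clamped") <- clamped
  r
}

#' Calibration of a model's absolute risks against observed outcomes
#'
#' The full calibration procedure for one model: assign records to
#' quantile groups of expected (predicted) 10-year risk, estimate the
#' observed risk of each group, fit the calibration line by OLS over the
#' group points, and recalibrate the expected risks with the fitted
#' affine map.
#'
#' @param expected Predicted 10-year risks, one per record.
#' @param followup A follow-up table from [build_followup()] aligned
#'   with `expected` (columns `time_years`, `event`).
#' @param n_groups Number of quantile groups (default 10, i.e. deciles).
#' @param estimator Observed-risk estimator, see [observed_risk()].
#' @param model_name Optional label.
#' @param by Values whose quantiles define the groups; defaults to
#'   `expected`. Point-score models are grouped on the predicted score
#'   (deciles of the score), which is finer than their stepwise risk
#'   scale but induces the same ordering.
#' @return An object of class `calibration_fit`: a list with
#'   `model_name`, `n_groups`, `estimator`, `table` (data frame with
#'   per-group `group`, `n`, `cases`, `expected`, `observed`,
#'   `recalibrated`; heavily tied scores can leave some quantile groups
#'   empty, and empty groups are omitted), `slope`, `intercept`,
#'   `n_clamped` and `groups` (the per-record group assignment).
#' @export
calibrate_model <- function(expected, followup, n_groups = 10L,
                            estimator = c("km", "crude"),
                            model_name = NA_character_, by = expected) {
  estimator <- match.arg(estimator)
  stopifnot(length(expected) == nrow(followup), length(by) == length(expected))
  if (anyNA(expected)) {
    stop("degenerate-input error: expected risks contain missing values",
         call. = FALSE)
  }
  g <- quantile_groups(by, n_groups)
  occupied <- sort(unique(g))
  tab <- do.call(rbind, lapply(occupied, function(k) {
    idx <- g == k
    data.frame(
      group = k, n = sum(idx),
      cases = sum(followup$event[idx]),
      expected = mean(expected[idx]),
      observed = observed_risk(followup$time_years[idx],
                               followup$event[idx],
                               estimator = estimator))
  }))
  line <- calibration_line(tab$expected, tab$observed)
  recal <- recalibrate(tab$expected, line[["slope"]], line[["intercept"]])
  tab$recalibrated <- as.numeric(recal)
  structure(list(model_name = model_name, n_groups = n_groups,
                 estimator = estimator, table = tab,
                 slope = line[["slope"]], intercept = line[["intercept"]],
                 n_clamped = attr(recal, "n_clamped"), groups = g),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Calibration", if (!is.na(x$model_name)) paste0("of ", x$model_name),
      "over", x$n_groups, "risk groups (", x$estimator,
      "observed risk )\n")
  cat(sprintf("  slope %.4f, intercept %.6f\n", x$slope, x$intercept))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Recalibrated risks for new predictions
#'
#' @param object A `calibration_fit`.
#' @param newrisks Predicted risks to recalibrate; defaults to the
#'   fitted group-level expected risks.
#' @param ... Unused.
#' @return Recalibrated risks (see [recalibrate()]).
#' @export
predict.calibration_fit <- function(object, newrisks = NULL, ...) {
  if (is.null(newrisks)) newrisks <- object$table$expected
  recalibrate(newrisks, object$slope, object$intercept)
}

#' Plot a calibration curve
#'
#' Observed versus expected group risks with the identity line and the
#' fitted calibration line.
#'
#' @param x A `calibration_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.calibration_fit <- function(x, ...) {
  tab <- x$table
  lim <- range(0, tab$expected, tab$observed)
  graphics::plot(tab$expected, tab$observed, xlim = lim, ylim = lim,
                 xlab = "Expected 10-year risk",
                 ylab = "Observed 10-year risk",
                 main = if (is.na(x$model_name)) "Calibration" else
                   paste("Calibration:", x$model_name), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}
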