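#' Construct a risk model specification from a list
#'
#' Normalises and validates a declarative risk-score specification. A
#' specification describes one published risk model: its functional form
#' (`logistic`, `cox` or integer `points`), the cohort columns it reads,
#' per-variable contributions (regression coefficients for continuous and
#' binary inputs, a level table for categorical inputs), the intercept or
#' baseline survival where the source article published one, an optional
#' points-to-absolute-risk lookup table, the native prediction horizon,
#' and the sex the model was developed in.
#'
#' Variable semantics:
#' \itemize{
#'   \item `continuous`: contribution `coef * (scale * x + offset)` with
#'     `transform` defaults `scale = 1`, `offset = 0`.
#'   \item `binary`: contribution `coef * x` for a logical column.
#'   \item `categorical`: an ordered list of levels, each a condition on
#'     the source value (`values`, a set, or `range`, a half-open
#'     interval `[lo, hi)`) with a numeric contribution (coefficient or
#'     integer points). Exactly one level is the reference and must
#'     contribute 0. Levels must be exhaustive and mutually exclusive
#'     over the declared domain.
#' }
#' Per-variable `missing_policy` is one of `"reference_level"` (missing
#' contributes 0), `"exclude_record"`, or a list
#' `list(impute_value = v)`.
#'
#' @param x A named list with fields `name`, `model_type`,
#'   `native_horizon_years`, `applicable_sex`, `intercept_or_baseline`
#'   (may be `NULL` for models publishing no absolute risk),
#'   `variables`, and optionally `risk_table`, `risk_table_gaps`,
#'   `provenance`.
#' @return An object of class `risk_model`.
#' @seealso [load_model_spec()] to read a specification file.
#' @export
as_risk_model <- function(x) {
  stopifnot(is.list(x))
  m <- list(
    name = x$name,
    model_type = x$model_type,
    native_horizon_years = x$native_horizon_years,
    applicable_sex = if (is.null(x$applicable_sex)) "both" else x$applicable_sex,
    intercept_or_baseline = x$intercept_or_baseline,
    variables = x$variables,
    risk_table = x$risk_table,
    risk_table_gaps = if (is.null(x$risk_table_gaps)) integer(0) else
      as.integer(x$risk_table_gaps),
    provenance = if (is.null(x$provenance)) "" else x$provenance
  )
  for (i in seq_along(m$variables)) {
    v <- m$variables[[i]]
    if (is.null(v$missing_policy)) v$missing_policy <- "reference_level"
    if (is.null(v$transform)) v$transform <- list(scale = 1, offset = 0)
    if (is.null(v$transform$scale)) v$transform$scale <- 1
    if (is.null(v$transform$offset)) v$transform$offset <- 0
    m$variables[[i]] <- v
  }
  class(m) <- "risk_model"
  validate_model_spec(m)
  m
}

#' Load a risk model specification file
#'
#' Reads a YAML model-specification file and validates it. The shipped
#' registry under `system.file("extdata", "models", package = "crcval")`
#' holds one file per model; their file names carry a `-synthetic`
#' suffix because the coefficient values are structural placeholders
#' (plausible effect directions and magnitudes), not transcriptions of
#' the source publications — see the `provenance` field of each file.
#'
#' @param path Path to a YAML model specification.
#' @return A validated `risk_model` object.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) {
    stop("configuration error: model spec file not found: ", path,
         call. = FALSE)
  }
  x <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("configuration error: cannot parse '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  as_risk_model(x)
}

#' Load a directory of model specifications
#'
#' @param dir Directory of `.yaml` model-spec files; defaults to the
#'   registry shipped with the package (nine models).
#' @return A named list of `risk_model` objects.
#' @export
load_model_registry <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "models", package = "crcval")
  }
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (length(files) == 0L) {
    stop("configuration error: no model spec files in ", dir, call. = FALSE)
  }
  models <- lapply(files, load_model_spec)
  names(models) <- vapply(models, `[[`, "", "name")
  if (anyDuplicated(names(models))) {
    stop("configuration error: duplicate model names in registry",
         call. = FALSE)
  }
  models
}

# domain of a categorical variable's source values, for exhaustiveness checks
.source_domain <- function(v) {
  sch <- cohort_schema()
  kind <- sch$columns[[v$source_column]]
  if (identical(kind, "logical")) return(c(TRUE, FALSE))
  sch$levels[[v$source_column]]
}

.level_is_range <- function(lv) !is.null(lv$range)

#' @rdname as_risk_model
#' @param model A `risk_model` object (or plain list) to check.
#' @return `model`, invisibly; otherwise an error naming the violated
#'   invariant.
#' @export
validate_model_spec <- function(model) {
  fail <- function(...) stop("model spec validation error [",
                             model$name, "]: ", ..., call. = FALSE)
  if (!is.character(model$name) || nchar(model$name) == 0L) {
    fail("field 'name' must be a non-empty string")
  }
  if (!model$model_type %in% c("logistic", "cox", "points")) {
    fail("field 'model_type' must be logistic, cox or points, got '",
         model$model_type, "'")
  }
  if (!is.numeric(model$native_horizon_years) ||
      model$native_horizon_years <= 0) {
    fail("field 'native_horizon_years' must be > 0")
  }
  if (!model$applicable_sex %in% c("male", "female", "both")) {
    fail("field 'applicable_sex' must be male, female or both")
  }
  if (model$model_type == "cox" && !is.null(model$intercept_or_baseline)) {
    s0 <- model$intercept_or_baseline
    if (!is.numeric(s0) || s0 <= 0 || s0 >= 1) {
      fail("field 'intercept_or_baseline': baseline survival S0 must lie ",
           "in (0, 1), got ", s0)
    }
  }
  if (model$model_type == "points" && !is.null(model$intercept_or_baseline)) {
    fail("field 'intercept_or_baseline' must be absent for points models")
  }
  if (length(model$variables) == 0L) fail("field 'variables' is empty")
  sch_cols <- names(cohort_schema()$columns)
  for (v in model$variables) {
    vfail <- function(...) fail("variable '", v$name, "': ", ...)
    if (is.null(v$source_column) || !v$source_column %in% sch_cols) {
      vfail("field 'source_column' (", v$source_column,
            ") is not a cohort schema column")
    }
    if (!v$kind %in% c("continuous", "categorical", "binary")) {
      vfail("field 'kind' must be continuous, categorical or binary")
    }
    mp <- v$missing_policy
    mp_ok <- (is.character(mp) && mp %in% c("reference_level",
                                            "exclude_record")) ||
      (is.list(mp) && !is.null(mp$impute_value))
    if (!mp_ok) vfail("field 'missing_policy' is invalid")
    if (v$kind %in% c("continuous", "binary")) {
      if (!is.numeric(v$coef)) vfail("field 'coef' must be numeric")
      next
    }
    # categorical invariants
    if (length(v$levels) < 2L) vfail("field 'levels' needs >= 2 entries")
    is_ref <- vapply(v$levels, function(lv) isTRUE(lv$reference), FALSE)
    if (sum(is_ref) != 1L) {
      vfail("exactly one level must be marked reference, found ", sum(is_ref))
    }
    if (abs(v$levels[[which(is_ref)]]$contribution) > 0) {
      vfail("the reference level must contribute 0")
    }
    ranged <- vapply(v$levels, .level_is_range, FALSE)
    if (any(ranged) && !all(ranged)) {
      vfail("levels must be all range-form or all values-form")
    }
    if (all(ranged)) {
      if (is.null(v$domain) || length(v$domain) != 2L) {
        vfail("range-form levels require a numeric 'domain: [lo, hi]'")
      }
      rng <- t(vapply(v$levels, function(lv) as.numeric(lv$range), numeric(2)))
      rng <- rng[order(rng[, 1L]), , drop = FALSE]
      if (any(rng[, 2L] <= rng[, 1L])) vfail("level range with hi <= lo")
      if (rng[1L, 1L] > v$domain[[1L]] ||
          rng[nrow(rng), 2L] < v$domain[[2L]]) {
        vfail("level ranges do not cover the declared domain")
      }
      if (nrow(rng) > 1L) {
        lo_next <- rng[-1L, 1L]; hi_prev <- rng[-nrow(rng), 2L]
        if (any(abs(lo_next - hi_prev) > 1e-9)) {
          vfail("level ranges overlap or leave gaps within the domain")
        }
      }
    } else {
      vals <- lapply(v$levels, `[[`, "values")
      if (any(vapply(vals, is.null, FALSE))) {
        vfail("each values-form level needs a 'values' set")
      }
      all_vals <- unlist(vals)
      if (anyDuplicated(all_vals)) {
        vfail("level value sets are not mutually exclusive")
      }
      dom <- .source_domain(v)
      if (!is.null(dom) && !setequal(all_vals, dom)) {
        vfail("level value sets are not exhaustive over the source domain {",
              paste(dom, collapse = ", "), "}")
      }
    }
  }
  if (model$model_type == "points") {
    contribs <- .points_contribution_sets(model)
    not_int <- vapply(contribs, function(s) any(abs(s - round(s)) > 1e-9),
                      FALSE)
    if (any(not_int)) fail("points model contributions must be integers")
    if (!is.null(model$risk_table)) .validate_risk_table(model, fail)
  }
  invisible(model)
}

# per-variable sets of achievable contributions for a points model
.points_contribution_sets <- function(model) {
  lapply(model$variables, function(v) {
    if (v$kind == "categorical") {
      unique(vapply(v$levels, `[[`, 0, "contribution"))
    } else if (v$kind == "binary") {
      unique(c(0, v$coef))
    } else {
      stop("model spec validation error [", model$name,
           "]: continuous variables are not supported in points models",
           call. = FALSE)
    }
  })
}

#' Achievable point totals of a points model
#'
#' Enumerates every point total reachable from the spec's level tables
#' (the Minkowski sum of per-variable contribution sets).
#'
#' @param model A points-type `risk_model`.
#' @return Sorted integer vector of achievable totals.
#' @export
achievable_points <- function(model) {
  stopifnot(inherits(model, "risk_model"), model$model_type == "points")
  totals <- 0
  for (s in .points_contribution_sets(model)) {
    totals <- unique(as.vector(outer(totals, s, `+`)))
  }
  sort(as.integer(round(totals)))
}

.validate_risk_table <- function(model, fail) {
  rt <- model$risk_table
  lo <- vapply(rt, `[[`, 0, "min"); hi <- vapply(rt, `[[`, 0, "max")
  risk <- vapply(rt, `[[`, 0, "risk")
  if (any(risk < 0 | risk > 1)) fail("risk_table risks must lie in [0, 1]")
  if (any(hi < lo)) fail("risk_table stratum with max < min")
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  if (length(lo) > 1L && any(lo[-1L] <= hi[-length(hi)])) {
    fail("risk_table strata overlap")
  }
  tot <- achievable_points(model)
  covered <- vapply(tot, function(t) any(t >= lo & t <= hi), FALSE)
  gap_ok <- tot %in% model$risk_table_gaps
  if (any(!covered & !gap_ok)) {
    fail("achievable point total(s) ",
         paste(tot[!covered & !gap_ok], collapse = ", "),
         " fall outside risk_table strata and are not declared gaps")
  }
  invisible(NULL)
}

#' Does a model publish absolute risk?
#'
#' Logistic and Cox specifications publish absolute risk when they carry
#' an intercept / baseline survival; points models when they carry a
#' points-to-risk lookup table. Models without published absolute risk
#' yield a relative score only (their calibration cannot be assessed).
#'
#' @param model A `risk_model`.
#' @return Logical scalar.
#' @export
provides_absolute_risk <- function(model) {
  if (model$model_type == "points") !is.null(model$risk_table)
  else !is.null(model$intercept_or_baseline)
}

# vectorised per-variable contribution; returns contributions and an
# exclusion flag for missing inputs under the exclude_record policy
.var_contribution <- function(v, cohort) {
  if (!v$source_column %in% names(cohort)) {
    stop("schema error: column '", v$source_column,
         "' required by variable '", v$name, "' is absent from the cohort",
         call. = FALSE)
  }
  x <- cohort[[v$source_column]]
  n <- length(x)
  excluded <- rep(FALSE, n)
  miss <- is.na(x)
  if (any(miss)) {
    mp <- v$missing_policy
    if (is.list(mp)) {
      x[miss] <- mp$impute_value
      miss[] <- FALSE
    } else if (identical(mp, "exclude_record")) {
      excluded <- miss
    } # reference_level: missing contributes 0 below
  }
  contrib <- numeric(n)
  idx <- which(!miss)
  if (v$kind == "continuous") {
    contrib[idx] <- v$coef *
      (v$transform$scale * as.numeric(x[idx]) + v$transform$offset)
  } else if (v$kind == "binary") {
    contrib[idx] <- v$coef * as.numeric(as.logical(x[idx]))
  } else {
    assigned <- rep(FALSE, n)
    for (lv in v$levels) {
      if (.level_is_range(lv)) {
        hit <- !miss & !assigned & as.numeric(x) >= lv$range[[1L]] &
          as.numeric(x) < lv$range[[2L]]
      } else {
        vals <- lv$values
        if (is.logical(x)) vals <- as.logical(vals)
        hit <- !miss & !assigned & (x %in% vals)
      }
      contrib[hit] <- lv$contribution
      assigned <- assigned | hit
    }
    if (any(!assigned & !miss)) {
      stop("evaluation error: variable '", v$name, "' has value(s) ",
           paste(unique(x[!assigned & !miss])[1:3], collapse = ", "),
           " outside its declared levels", call. = FALSE)
    }
  }
  list(contribution = contrib, excluded = excluded)
}

#' Score a cohort under a risk model specification
#'
#' Evaluates the model's linear predictor (or point total) for every
#' record, applies per-variable missing-data policies, marks records
#' excluded under `exclude_record` policies or (optionally) when the
#' participant's sex falls outside the model's `applicable_sex`, and
#' attaches the model's absolute risk at its native horizon and
#' converted to 10 years where the model publishes one.
#'
#' @param model A `risk_model`.
#' @param cohort A schema-conforming cohort data frame.
#' @param drop_variables Character vector of variable names to omit from
#'   the score (used e.g. to drop an aspirin term whose input is
#'   observed only in a medical-history subgroup).
#' @param enforce_sex If `TRUE` (default), records whose sex is outside
#'   `applicable_sex` are marked excluded; if `FALSE` they are scored
#'   anyway (validation of a sex-specific model in both sexes) and a
#'   warning is issued once.
#' @return A data frame with columns `id`, `score`
#'   (linear predictor or point total), `risk_native`, `risk_10y`
#'   (`NA` when the model publishes no absolute risk), `excluded`,
#'   `exclude_reason`.
#' @export
score_cohort <- function(model, cohort, drop_variables = character(),
                         enforce_sex = TRUE) {
  stopifnot(inherits(model, "risk_model"))
  n <- nrow(cohort)
  vars <- model$variables
  if (length(drop_variables) > 0L) {
    keep <- !vapply(vars, `[[`, "", "name") %in% drop_variables
    vars <- vars[keep]
    if (all(keep)) {
      warning("drop_variables named no variable of model '", model$name, "'")
    }
  }
  score <- numeric(n)
  excluded <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  for (v in vars) {
    vc <- .var_contribution(v, cohort)
    score <- score + vc$contribution
    newly <- vc$excluded & !excluded
    reason[newly] <- paste0("missing ", v$source_column)
    excluded <- excluded | vc$excluded
  }
  if (model$model_type == "logistic" &&
      !is.null(model$intercept_or_baseline)) {
    score <- score + model$intercept_or_baseline
  }
  if (model$applicable_sex != "both") {
    off_sex <- cohort$sex != model$applicable_sex
    if (any(off_sex)) {
      if (enforce_sex) {
        reason[off_sex & !excluded] <- "sex outside applicable_sex"
        excluded <- excluded | off_sex
      } else {
        warning("model '", model$name, "' was developed in ",
                model$applicable_sex, "s only; scoring ", sum(off_sex),
                " record(s) of the other sex", call. = FALSE)
      }
    }
  }
  score[excluded] <- NA_real_
  risk_native <- rep(NA_real_, n)
  ok <- !excluded
  if (provides_absolute_risk(model) && any(ok)) {
    risk_native[ok] <- risk_from_score(model, score[ok])
  }
  risk_10y <- convert_horizon(risk_native, model$native_horizon_years, 10)
  data.frame(id = cohort$id, score = score, risk_native = risk_native,
             risk_10y = risk_10y, excluded = excluded,
             exclude_reason = reason, stringsAsFactors = FALSE)
}

#' Evaluate a risk model on a single record
#'
#' Single-record convenience wrapper around [score_cohort()].
#'
#' @param model A `risk_model`.
#' @param record A one-row schema-conforming data frame.
#' @param ... Passed to [score_cohort()].
#' @return A list with elements `model_name`,
#'   `linear_predictor_or_points`, `absolute_risk_10y`, `excluded`,
#'   `exclude_reason`.
#' @export
evaluate <- function(model, record, ...) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  s <- score_cohort(model, record, ...)
  list(model_name = model$name,
       linear_predictor_or_points = s$score,
       absolute_risk_10y = s$risk_10y,
       excluded = s$excluded,
       exclude_reason = s$exclude_reason)
}

#' Absolute risk at the model's native horizon from a score
#'
#' Applies the model's published score-to-risk form: the inverse logit
#' for logistic models, `1 - S0^exp(score)` for Cox models, and the
#' points-to-risk lookup table for point systems. Models publishing no
#' absolute risk return `NA` (the score is relative only).
#'
#' @param model A `risk_model`.
#' @param score Numeric vector of scores produced by [score_cohort()]
#'   under the same model.
#' @return Numeric vector of risks in `[0, 1]`, or `NA` where undefined.
#' @export
risk_from_score <- function(model, score) {
  stopifnot(inherits(model, "risk_model"))
  if (!provides_absolute_risk(model)) return(rep(NA_real_, length(score)))
  switch(model$model_type,
    logistic = stats::plogis(score),
    cox = 1 - model$intercept_or_baseline ^ exp(score),
    points = {
      rt <- model$risk_table
      lo <- vapply(rt, `[[`, 0, "min"); hi <- vapply(rt, `[[`, 0, "max")
      rk <- vapply(rt, `[[`, 0, "risk")
      out <- rep(NA_real_, length(score))
      for (i in seq_along(lo)) {
        out[!is.na(score) & score >= lo[i] & score <= hi[i]] <- rk[i]
      }
      uncovered <- !is.na(score) & is.na(out) &
        !(round(score) %in% model$risk_table_gaps)
      if (any(uncovered)) {
        stop("out-of-range error: point total(s) ",
             paste(unique(score[uncovered])[1:3], collapse = ", "),
             " outside the risk_table coverage of model '", model$name, "'",
             call. = FALSE)
      }
      out
    }
  )
}

#' Convert a cumulative risk between prediction horizons
#'
#' Rescales a cumulative incidence from one horizon to another under a
#' constant-hazard (exponential waiting time) assumption:
#' `1 - (1 - risk)^(to_years / from_years)`. Used to bring a 20-year
#' risk model onto the 10-year scale of the validation analysis.
#'
#' @param risk Numeric vector of probabilities in `[0, 1]` (`NA` passed
#'   through).
#' @param from_years,to_years Positive horizon lengths in years.
#' @return Converted risks.
#' @export
convert_horizon <- function(risk, from_years, to_years) {
  stopifnot(from_years > 0, to_years > 0)
  if (any(risk < 0 | risk > 1, na.rm = TRUE)) {
    stop("domain error: risk outside [0, 1]", call. = FALSE)
  }
  # stable evaluation of 1 - (1 - risk)^(to/from)
  -expm1(to_years / from_years * log1p(-risk))
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> ", x$name, "\n", sep = "")
  cat("  type:            ", x$model_type, "\n", sep = "")
  cat("  native horizon:  ", x$native_horizon_years, " years\n", sep = "")
  cat("  developed in:    ", x$applicable_sex,
      if (x$applicable_sex == "both") " sexes" else "s only", "\n", sep = "")
  cat("  absolute risk:   ",
      if (provides_absolute_risk(x)) "published" else
        "not published (relative score only)", "\n", sep = "")
  cat("  variables:       ",
      paste(vapply(x$variables, `[[`, "", "name"), collapse = ", "),
      "\n", sep = "")
  if (nchar(x$provenance)) cat("  provenance:      ", x$provenance, "\n")
  invisible(x)
}

#' Predict method for risk model specifications
#'
#' @param object A `risk_model`.
#' @param newdata A schema-conforming cohort data frame.
#' @param type `"lp"` for the linear predictor / point total, `"risk"`
#'   for the absolute 10-year risk (`NA` if the model publishes none).
#' @param ... Passed to [score_cohort()].
#' @return Numeric vector.
#' @export
predict.risk_model <- function(object, newdata,
                               type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  s <- score_cohort(object, newdata, ...)
  if (type == "lp") s$score else s$risk_10y
}
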