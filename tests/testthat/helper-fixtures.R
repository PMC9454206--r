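# Fixtures built in code: toy cohort records, toy model specs, and
# brute-force oracles used across test files.

# One or more full schema rows with sensible defaults, overridable per
# column; vectors recycle to `n`.
toy_records <- function(n = 1L, ...) {
  defaults <- list(
    id = seq_len(n), age = 45, sex = "female", region = "urban_1",
    urban = TRUE, bmi = 22, height_cm = 158, waist_cm = 78,
    smoking_status = "never", alcohol_weekly = FALSE,
    alcohol_category = "none", diabetes = FALSE, physical_activity = 20,
    sitting_time = "low", red_meat_freq = "weekly",
    processed_meat_freq = "never", vegetable_freq = "daily",
    dairy_freq = "never", egg_freq = "weekly",
    defecation_frequency = "daily", education = "primary",
    marital_status = "married", nsaid_use = FALSE,
    metabolic_syndrome = FALSE, chd_history = FALSE, aspirin_use = NA,
    prior_intestinal_cancer = FALSE, entry_day = 0L, exit_day = 3652.5,
    exit_reason = "admin", icd10 = NA_character_
  )
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(data.frame, c(defaults, stringsAsFactors = FALSE))
}

# toy logistic spec: intercept + one continuous + one categorical +
# one binary term
toy_logistic_spec <- function(intercept = -2) {
  as_risk_model(list(
    name = "toy_logistic", model_type = "logistic",
    native_horizon_years = 10, applicable_sex = "both",
    intercept_or_baseline = intercept,
    variables = list(
      list(name = "age", source_column = "age", kind = "continuous",
           coef = 0.1, transform = list(scale = 1, offset = -45)),
      list(name = "smoking", source_column = "smoking_status",
           kind = "categorical",
           levels = list(
             list(values = "never", contribution = 0, reference = TRUE),
             list(values = "ex_regular", contribution = 0.3),
             list(values = "current", contribution = 0.6))),
      list(name = "diabetes", source_column = "diabetes", kind = "binary",
           coef = 0.5))
  ))
}

# toy points spec with three variables and a full-coverage risk table
toy_points_spec <- function(risk_table = list(
                              list(min = 0, max = 2, risk = 0.001),
                              list(min = 3, max = 7, risk = 0.005))) {
  as_risk_model(list(
    name = "toy_points", model_type = "points",
    native_horizon_years = 10, applicable_sex = "both",
    variables = list(
      list(name = "age_band", source_column = "age", kind = "categorical",
           domain = c(30, 80),
           levels = list(
             list(range = c(30, 55), contribution = 0, reference = TRUE),
             list(range = c(55, Inf), contribution = 2))),
      list(name = "smoking", source_column = "smoking_status",
           kind = "categorical",
           levels = list(
             list(values = "never", contribution = 0, reference = TRUE),
             list(values = "ex_regular", contribution = 1),
             list(values = "current", contribution = 2))),
      list(name = "diabetes", source_column = "diabetes", kind = "binary",
           coef = 3)),
    risk_table = risk_table
  ))
}

toy_cox_spec <- function(s0 = 0.99) {
  as_risk_model(list(
    name = "toy_cox", model_type = "cox",
    native_horizon_years = 10, applicable_sex = "both",
    intercept_or_baseline = s0,
    variables = list(
      list(name = "age", source_column = "age", kind = "continuous",
           coef = 0.05, transform = list(scale = 1, offset = -45)))
  ))
}

# exhaustive Mann-Whitney AUC with half-credit ties
auc_oracle <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive Harrell concordance via full pair matrices: usable pair =
# event vs strictly longer-surviving comparator, score ties 0.5
concordance_oracle <- function(times, events, scores) {
  usable <- outer(as.logical(events), rep(TRUE, length(times)), `&`) &
    outer(times, times, `<`)
  credit <- outer(scores, scores, `>`) + 0.5 * outer(scores, scores, `==`)
  if (sum(usable) == 0) return(NA_real_)
  sum(credit[usable]) / sum(usable)
}

shipped_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- load_model_registry()
    reg
  }
})
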