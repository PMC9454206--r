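test_that("the shipped registry loads nine distinct, valid models", {
  reg <- shipped_registry()
  expect_length(reg, 9L)
  expect_setequal(names(reg),
                  c("driver", "ma_point", "ma_cox", "guo", "chen", "betes",
                    "aleksandrova", "imperiale", "hong"))
  # Table-2-style metadata: sex restriction, horizon, absolute risk
  male_only <- c("driver", "ma_point", "ma_cox", "guo")
  for (nm in names(reg)) {
    expect_equal(reg[[nm]]$applicable_sex,
                 if (nm %in% male_only) "male" else "both", info = nm)
  }
  expect_equal(reg$driver$native_horizon_years, 20)
  other <- setdiff(names(reg), "driver")
  expect_true(all(vapply(reg[other], `[[`, 0,
                         "native_horizon_years") == 10))
  with_risk <- names(which(vapply(reg, provides_absolute_risk, FALSE)))
  expect_setequal(with_risk,
                  c("driver", "ma_point", "guo", "imperiale", "hong"))
})

test_that("spec invariants are enforced at load time", {
  bad_s0 <- list(name = "bad", model_type = "cox",
                 native_horizon_years = 10, applicable_sex = "both",
                 intercept_or_baseline = 1.2,
                 variables = list(list(name = "age", source_column = "age",
                                       kind = "continuous", coef = 0.1)))
  expect_error(as_risk_model(bad_s0), "S0 must lie")

  no_ref <- list(name = "bad", model_type = "logistic",
                 native_horizon_years = 10, applicable_sex = "both",
                 intercept_or_baseline = 0,
                 variables = list(list(
                   name = "smoking", source_column = "smoking_status",
                   kind = "categorical",
                   levels = list(list(values = "never", contribution = 0.1),
                                 list(values = c("ex_regular", "current"),
                                      contribution = 0.2)))))
  expect_error(as_risk_model(no_ref), "reference")

  non_exhaustive <- list(name = "bad", model_type = "logistic",
                         native_horizon_years = 10, applicable_sex = "both",
                         intercept_or_baseline = 0,
                         variables = list(list(
                           name = "smoking", source_column = "smoking_status",
                           kind = "categorical",
                           levels = list(
                             list(values = "never", contribution = 0,
                                  reference = TRUE),
                             list(values = "current", contribution = 0.2)))))
  expect_error(as_risk_model(non_exhaustive), "exhaustive")

  bad_col <- list(name = "bad", model_type = "logistic",
                  native_horizon_years = 10, applicable_sex = "both",
                  intercept_or_baseline = 0,
                  variables = list(list(name = "x", source_column = "nope",
                                        kind = "continuous", coef = 1)))
  expect_error(as_risk_model(bad_col), "schema column")
})

test_that("points risk tables must cover achievable totals", {
  expect_error(
    toy_points_spec(risk_table = list(list(min = 0, max = 4, risk = 0.002))),
    "outside risk_table strata")
  # declared gaps are accepted
  m <- as_risk_model(list(
    name = "gappy", model_type = "points", native_horizon_years = 10,
    applicable_sex = "both",
    variables = list(list(name = "diabetes", source_column = "diabetes",
                          kind = "binary", coef = 3)),
    risk_table = list(list(min = 0, max = 0, risk = 0.001)),
    risk_table_gaps = 3))
  expect_equal(achievable_points(m), c(0L, 3L))
  expect_true(is.na(risk_from_score(m, 3)))
})

test_that("evaluation reduces to the intercept at the reference profile", {
  m <- toy_logistic_spec(intercept = -2)
  rec <- toy_records(age = 45, smoking_status = "never", diabetes = FALSE)
  res <- evaluate(m, rec)
  expect_identical(res$linear_predictor_or_points, -2)
  expect_equal(res$absolute_risk_10y, stats::plogis(-2))
  expect_false(res$excluded)
})

test_that("point totals add per-variable contributions", {
  m <- toy_points_spec()
  # age 60 -> 2 points, smoking never -> 0, diabetes TRUE -> 3: total 5
  rec <- toy_records(age = 60, smoking_status = "never", diabetes = TRUE)
  res <- evaluate(m, rec)
  expect_identical(res$linear_predictor_or_points, 5)
  expect_equal(res$absolute_risk_10y, 0.005)
})

test_that("sex-restricted models mark off-sex records excluded", {
  reg <- shipped_registry()
  female <- toy_records(sex = "female", bmi = 22, waist_cm = 70)
  res <- evaluate(reg$guo, female)
  expect_true(res$excluded)
  expect_match(res$exclude_reason, "sex")
  # the pipeline-level override scores anyway, with a warning
  expect_warning(s <- score_cohort(reg$guo, female, enforce_sex = FALSE),
                 "developed in")
  expect_false(s$excluded)
  expect_false(is.na(s$score))
})

test_that("missing inputs follow the per-variable policy", {
  m <- toy_logistic_spec(intercept = 0)
  rec <- toy_records(smoking_status = NA_character_, age = 45)
  expect_identical(evaluate(m, rec)$linear_predictor_or_points, 0)

  m_excl <- as_risk_model(list(
    name = "excl", model_type = "logistic", native_horizon_years = 10,
    applicable_sex = "both", intercept_or_baseline = 0,
    variables = list(list(name = "bmi", source_column = "bmi",
                          kind = "continuous", coef = 0.1,
                          missing_policy = "exclude_record"))))
  res <- evaluate(m_excl, toy_records(bmi = NA_real_))
  expect_true(res$excluded)
  expect_match(res$exclude_reason, "missing bmi")

  m_imp <- as_risk_model(list(
    name = "imp", model_type = "logistic", native_horizon_years = 10,
    applicable_sex = "both", intercept_or_baseline = 0,
    variables = list(list(name = "asp", source_column = "aspirin_use",
                          kind = "binary", coef = -0.4,
                          missing_policy = list(impute_value = FALSE)))))
  expect_identical(evaluate(m_imp, toy_records(aspirin_use = NA))$
                     linear_predictor_or_points, 0)
  expect_equal(evaluate(m_imp, toy_records(aspirin_use = TRUE,
                                           chd_history = TRUE))$
                 linear_predictor_or_points, -0.4)
})

test_that("score-to-risk follows the published inverse forms", {
  expect_equal(risk_from_score(toy_logistic_spec(), 0), 0.5)
  cox <- toy_cox_spec(s0 = 0.99)
  expect_equal(risk_from_score(cox, 0), 0.01)
  expect_equal(risk_from_score(cox, log(2)), 1 - 0.99^2)
  # models without published absolute risk are undefined
  reg <- shipped_registry()
  expect_true(is.na(risk_from_score(reg$ma_cox, 1.3)))
  expect_true(is.na(risk_from_score(reg$chen, 4)))
  # out-of-coverage point totals error
  expect_error(risk_from_score(toy_points_spec(), 99), "out-of-range")
})

test_that("risk is strictly increasing in score for logistic and cox", {
  grid <- seq(-6, 6, length.out = 201)
  for (m in list(toy_logistic_spec(), toy_cox_spec())) {
    r <- risk_from_score(m, grid)
    expect_true(all(diff(r) > 0), info = m$name)
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("horizon conversion matches the exponential closed form", {
  expect_equal(convert_horizon(0, 20, 10), 0)
  expect_equal(convert_horizon(0.37, 7, 7), 0.37)
  expect_equal(convert_horizon(0.2, 20, 10), 1 - 0.8^0.5)
  # cross-check against hazard algebra: h = -log(1 - r) / t
  r <- 0.2
  h <- -log(1 - r) / 20
  expect_equal(convert_horizon(r, 20, 10), 1 - exp(-h * 10))
  expect_error(convert_horizon(1.2, 20, 10), "domain error")
  # round-trip identity on a grid
  rr <- seq(0, 0.99, length.out = 100)
  expect_equal(convert_horizon(convert_horizon(rr, 20, 10), 10, 20), rr,
               tolerance = 1e-12)
})

test_that("evaluation is invariant to variable order in the spec", {
  m <- toy_logistic_spec()
  m_rev <- m
  m_rev$variables <- rev(m$variables)
  set.seed(7)
  recs <- toy_records(20, age = runif(20, 30, 79),
                      smoking_status = sample(c("never", "ex_regular",
                                                "current"), 20, TRUE),
                      diabetes = sample(c(TRUE, FALSE), 20, TRUE))
  # equal up to floating-point summation order
  expect_equal(score_cohort(m, recs)$score,
               score_cohort(m_rev, recs)$score, tolerance = 1e-12)
})

test_that("every achievable total of shipped points models is mapped", {
  reg <- shipped_registry()
  for (nm in c("ma_point", "guo")) {
    tot <- achievable_points(reg[[nm]])
    expect_no_error(risk_from_score(reg[[nm]], tot))
  }
})

test_that("drop_variables removes exactly the named term", {
  reg <- shipped_registry()
  rec <- toy_records(chd_history = TRUE, aspirin_use = TRUE, age = 60,
                     sex = "male", smoking_status = "current",
                     alcohol_weekly = TRUE)
  full <- score_cohort(reg$hong, rec)$score
  no_asp <- score_cohort(reg$hong, rec, drop_variables = "aspirin")$score
  expect_equal(full - no_asp, -0.35)
})
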