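#' Parameters of the synthetic cohort generator
#'
#' Builds the parameter object controlling [generate_cohort()] and
#' [simulate_outcomes()]. Defaults emulate a large middle-aged Chinese
#' population-based cohort: ages 30--79, ten regions (five urban, five
#' rural), lifestyle and medical-history covariates with realistic
#' marginal distributions, an aspirin variable observable only in the
#' coronary-heart-disease subgroup, a 10-year cumulative colorectal
#' cancer incidence of about 0.6\%, competing non-CRC mortality, loss to
#' follow-up, and administrative censoring at 10 years.
#'
#' The outcome process is proportional hazards: each participant's CRC
#' hazard is `lambda0 * exp(lp)` with `lp` the generating linear
#' predictor (see `true_effects`), and `lambda0` is calibrated so the
#' marginal crude 10-year CRC incidence matches `baseline_hazard_10y`
#' in expectation (closed form under exponential waiting times).
#'
#' `true_effects` is a named log-hazard vector over derived covariates
#' `age` (per year, centred at 51), `male`, `smoking_ex`,
#' `smoking_current`, `alcohol_weekly`, `bmi` (per kg/m^2, centred at
#' 23.7), `diabetes`, `physical_activity` (per MET-h/day, centred at
#' 20). Unnamed effects default to 0, so a single-covariate generating
#' model is obtained by passing a one-element vector.
#'
#' @param n Number of participants.
#' @param seed Integer RNG seed; identical parameters imply
#'   byte-identical cohorts.
#' @param ... Named overrides of the defaults listed by
#'   `cohort_params()` (e.g. `p_female`, `diabetes_prev`,
#'   `true_effects`, `baseline_hazard_10y`, `competing_death_rate`,
#'   `ltfu_rate`, `site_split`).
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n, seed = 1L, ...) {
  p <- list(
    n = as.integer(n), seed = as.integer(seed),
    age_range = c(30, 79), age_mean = 51, age_sd = 10.5,
    p_female = 0.59,
    regions = c(paste0("urban_", 1:5), paste0("rural_", 1:5)),
    bmi_mean = 23.7, bmi_sd = 3.3, bmi_missing = 4e-6,
    height_mean = c(male = 165, female = 153), height_sd = 6,
    waist_mean = c(male = 85, female = 80), waist_sd = 9.5,
    smoking_probs = list(male = c(never = 0.35, ex_regular = 0.12,
                                  current = 0.53),
                         female = c(never = 0.97, ex_regular = 0.01,
                                    current = 0.02)),
    alcohol_weekly_prob = c(male = 0.33, female = 0.02),
    diabetes_prev = 0.059,
    pa_meanlog = log(20), pa_sdlog = 0.45,
    sitting_probs = c(low = 0.3, medium = 0.5, high = 0.2),
    diet_probs = list(
      red_meat_freq = c(never = 0.10, monthly = 0.25, weekly = 0.45,
                        daily = 0.20),
      processed_meat_freq = c(never = 0.45, monthly = 0.30, weekly = 0.20,
                              daily = 0.05),
      vegetable_freq = c(never = 0.01, monthly = 0.04, weekly = 0.25,
                         daily = 0.70),
      dairy_freq = c(never = 0.55, monthly = 0.20, weekly = 0.15,
                     daily = 0.10),
      egg_freq = c(never = 0.10, monthly = 0.25, weekly = 0.40,
                   daily = 0.25),
      sugar_freq = c(never = 0.35, monthly = 0.30, weekly = 0.25,
                     daily = 0.10)),
    defecation_probs = c(lt_daily = 0.15, daily = 0.75, gt_daily = 0.10),
    education_probs = c(none = 0.20, primary = 0.35, middle = 0.25,
                        high_school = 0.12, tertiary = 0.08),
    marital_probs = c(married = 0.90, not_married = 0.10),
    nsaid_prev = 0.02, metsyn_prev = 0.15,
    chd_prev = 0.03, aspirin_prob_chd = 0.25,
    prior_intestinal_cancer_prev = 6e-4,
    true_effects = c(age = 0.075, male = 0.25, smoking_ex = 0.15,
                     smoking_current = 0.35, alcohol_weekly = 0.20,
                     bmi = 0.02, diabetes = 0.30,
                     physical_activity = -0.01),
    baseline_hazard_10y = 0.0058,
    competing_death_rate = 0.008,
    ltfu_rate = 0.001,
    site_split = c(C18.0 = 0.04, C18.1 = 0.01, C18.2 = 0.06, C18.3 = 0.02,
                   C18.4 = 0.03, C18.5 = 0.02, C18.6 = 0.04, C18.7 = 0.18,
                   C18.8 = 0.02, C18.9 = 0.08, C19 = 0.10, C20 = 0.40),
    recruitment_days = 1460L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L) {
    stop("cohort params validation error: unknown parameter(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  p[names(dots)] <- dots
  class(p) <- "cohort_params"
  validate_cohort_params(p)
  p
}

#' @rdname cohort_params
#' @param params A `cohort_params` object to check.
#' @export
validate_cohort_params <- function(params) {
  fail <- function(...) stop("cohort params validation error: ", ...,
                             call. = FALSE)
  if (!is.numeric(params$n) || params$n < 1) fail("n must be >= 1")
  probs <- c(params$p_female, params$diabetes_prev, params$chd_prev,
             params$aspirin_prob_chd, params$nsaid_prev,
             params$metsyn_prev, params$prior_intestinal_cancer_prev,
             params$baseline_hazard_10y, params$alcohol_weekly_prob,
             params$bmi_missing)
  if (any(probs < 0 | probs > 1)) fail("a probability lies outside [0, 1]")
  if (abs(sum(params$site_split) - 1) > 1e-9) {
    fail("site_split must sum to 1 (got ", sum(params$site_split), ")")
  }
  urban <- grepl("^urban_", params$regions)
  if (length(params$regions) != 10L || sum(urban) != 5L) {
    fail("regions must be 10 labels, 5 prefixed urban_ and 5 rural_")
  }
  if (params$competing_death_rate < 0 || params$ltfu_rate < 0) {
    fail("annual rates must be non-negative")
  }
  invisible(params)
}

.sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

.rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate baseline covariates for a synthetic cohort
#'
#' Samples `params$n` participant records from the marginal
#' distributions in `params`. Covariates are sampled independently
#' given sex and region. Follow-up fields are left unfilled; see
#' [simulate_outcomes()].
#'
#' @param params A [cohort_params()] object.
#' @return A schema-conforming data frame without exit fields.
#' @export
generate_cohort <- function(params) {
  validate_cohort_params(params)
  set.seed(params$seed)
  n <- params$n
  sex <- ifelse(stats::runif(n) < params$p_female, "female", "male")
  male <- sex == "male"
  region <- sample(params$regions, n, replace = TRUE)
  bmi <- pmin(pmax(stats::rnorm(n, params$bmi_mean, params$bmi_sd), 14), 45)
  bmi[stats::runif(n) < params$bmi_missing] <- NA_real_
  smoking <- character(n)
  smoking[male] <- .sample_cat(sum(male), params$smoking_probs$male)
  smoking[!male] <- .sample_cat(sum(!male), params$smoking_probs$female)
  alc_week <- stats::runif(n) <
    params$alcohol_weekly_prob[ifelse(male, "male", "female")]
  alc_cat <- ifelse(alc_week,
                    ifelse(stats::runif(n) < 0.7, "weekly", "daily"),
                    ifelse(stats::runif(n) < 0.6, "none", "occasional"))
  chd <- stats::runif(n) < params$chd_prev
  aspirin <- rep(NA, n)
  aspirin[chd] <- stats::runif(sum(chd)) < params$aspirin_prob_chd
  cohort <- data.frame(
    id = seq_len(n),
    age = .rtnorm(n, params$age_mean, params$age_sd,
                  params$age_range[1], params$age_range[2]),
    sex = sex, region = region, urban = grepl("^urban_", region),
    bmi = bmi,
    height_cm = stats::rnorm(n, params$height_mean[ifelse(male, "male",
                                                          "female")],
                             params$height_sd),
    waist_cm = stats::rnorm(n, params$waist_mean[ifelse(male, "male",
                                                        "female")],
                            params$waist_sd),
    smoking_status = smoking,
    alcohol_weekly = alc_week, alcohol_category = alc_cat,
    diabetes = stats::runif(n) < params$diabetes_prev,
    physical_activity = pmin(stats::rlnorm(n, params$pa_meanlog,
                                           params$pa_sdlog), 80),
    sitting_time = .sample_cat(n, params$sitting_probs),
    red_meat_freq = .sample_cat(n, params$diet_probs$red_meat_freq),
    processed_meat_freq = .sample_cat(n, params$diet_probs$processed_meat_freq),
    vegetable_freq = .sample_cat(n, params$diet_probs$vegetable_freq),
    dairy_freq = .sample_cat(n, params$diet_probs$dairy_freq),
    egg_freq = .sample_cat(n, params$diet_probs$egg_freq),
    sugar_freq = .sample_cat(n, params$diet_probs$sugar_freq),
    defecation_frequency = .sample_cat(n, params$defecation_probs),
    education = .sample_cat(n, params$education_probs),
    marital_status = .sample_cat(n, params$marital_probs),
    nsaid_use = stats::runif(n) < params$nsaid_prev,
    metabolic_syndrome = stats::runif(n) < params$metsyn_prev,
    chd_history = chd, aspirin_use = aspirin,
    prior_intestinal_cancer = stats::runif(n) <
      params$prior_intestinal_cancer_prev,
    entry_day = sample.int(params$recruitment_days, n, replace = TRUE) - 1L,
    stringsAsFactors = FALSE
  )
  validate_cohort(cohort, require_exit = FALSE)
  cohort
}

#' Generating-model linear predictor
#'
#' The log-hazard linear predictor of the data-generating proportional
#' hazards model, centred at typical covariate values so the baseline
#' hazard refers to a typical participant.
#'
#' @param cohort A baseline cohort data frame.
#' @param params A [cohort_params()] object.
#' @return Numeric vector, one element per record.
#' @export
generating_linear_predictor <- function(cohort, params) {
  eff <- params$true_effects
  g <- function(name) if (is.na(eff[name])) 0 else eff[[name]]
  bmi <- ifelse(is.na(cohort$bmi), params$bmi_mean, cohort$bmi)
  g("age") * (cohort$age - 51) +
    g("male") * (cohort$sex == "male") +
    g("smoking_ex") * (cohort$smoking_status == "ex_regular") +
    g("smoking_current") * (cohort$smoking_status == "current") +
    g("alcohol_weekly") * cohort$alcohol_weekly +
    g("bmi") * (bmi - params$bmi_mean) +
    g("diabetes") * cohort$diabetes +
    g("physical_activity") * (cohort$physical_activity - 20)
}

# Calibrates the baseline CRC hazard so that the expected crude 10-year
# cumulative incidence (CRC as first event, before competing death /
# loss to follow-up) equals the target. Closed form under exponential
# waiting times: P(crc first, <=10y | lp) =
#   h/(h+mu) * (1 - exp(-(h+mu)*10)),  h = lambda0*exp(lp).
.calibrate_lambda0 <- function(lp, params) {
  target <- params$baseline_hazard_10y
  if (target == 0) return(0)
  mu <- params$competing_death_rate + params$ltfu_rate
  crude <- function(lambda0) {
    h <- lambda0 * exp(lp)
    tot <- h + mu
    p <- ifelse(tot > 0, h / tot * (1 - exp(-tot * 10)), 0)
    mean(p) - target
  }
  stats::uniroot(crude, c(1e-12, 5), tol = 1e-14)$root
}

#' Baseline CRC hazard implied by the generator's calibration
#'
#' @inheritParams generating_linear_predictor
#' @return The annual baseline hazard `lambda0` such that the expected
#'   crude 10-year CRC incidence over `cohort` equals
#'   `params$baseline_hazard_10y`.
#' @export
baseline_crc_hazard <- function(cohort, params) {
  .calibrate_lambda0(generating_linear_predictor(cohort, params), params)
}

#' True net 10-year CRC risk of each synthetic participant
#'
#' The cause-specific (net) probability of CRC within 10 years under the
#' generating model, `1 - exp(-lambda0 * exp(lp) * 10)` — the quantity a
#' perfectly calibrated risk model would predict, and the estimand of
#' the Kaplan-Meier-based observed risk used in calibration.
#'
#' @inheritParams generating_linear_predictor
#' @return Numeric vector of probabilities.
#' @export
true_risk <- function(cohort, params) {
  lambda0 <- baseline_crc_hazard(cohort, params)
  1 - exp(-lambda0 * exp(generating_linear_predictor(cohort, params)) * 10)
}

.rexp_rate <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

#' Simulate follow-up outcomes for a synthetic cohort
#'
#' Draws each participant's CRC event time from the proportional-hazards
#' generating model (exponential waiting time with hazard
#' `lambda0 * exp(lp)`), independent exponential competing death and
#' loss-to-follow-up times, and applies administrative censoring at 10
#' years; the earliest of the four determines the exit. CRC events
#' receive an ICD-10 site code drawn from `params$site_split`.
#'
#' Uses an RNG stream derived from `params$seed` (offset from the one
#' used for covariate sampling), so a full cohort build is reproducible
#' from the single seed.
#'
#' @param cohort A baseline cohort (no exit fields), typically from
#'   [generate_cohort()].
#' @param params The same [cohort_params()] object.
#' @return The cohort with `exit_day`, `exit_reason` and `icd10` filled.
#' @export
simulate_outcomes <- function(cohort, params) {
  validate_cohort_params(params)
  if ("exit_reason" %in% names(cohort) && !all(is.na(cohort$exit_reason))) {
    stop("simulate_outcomes: cohort already has exit fields", call. = FALSE)
  }
  set.seed(params$seed + 500009L)
  n <- nrow(cohort)
  lp <- generating_linear_predictor(cohort, params)
  lambda0 <- .calibrate_lambda0(lp, params)
  h <- lambda0 * exp(lp)
  t_crc <- ifelse(h > 0, .rexp_rate(n, 1) / h, Inf)
  t_death <- .rexp_rate(n, params$competing_death_rate)
  t_ltfu <- .rexp_rate(n, params$ltfu_rate)
  t_admin <- rep(10, n)
  tt <- pmin(t_crc, t_death, t_ltfu, t_admin)
  reason <- rep("admin", n)
  reason[tt == t_ltfu] <- "ltfu"
  reason[tt == t_death] <- "death_other"
  reason[tt == t_crc] <- "crc"
  icd <- rep(NA_character_, n)
  is_crc <- reason == "crc"
  if (any(is_crc)) {
    icd[is_crc] <- .sample_cat(sum(is_crc), params$site_split)
  }
  cohort$exit_day <- cohort$entry_day + tt * 365.25
  cohort$exit_reason <- reason
  cohort$icd10 <- icd
  validate_cohort(cohort)
  cohort
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_cohort()] followed by
#' [simulate_outcomes()].
#'
#' @inheritParams generate_cohort
#' @return A schema-conforming cohort with follow-up fields.
#' @export
synthetic_cohort <- function(params) {
  simulate_outcomes(generate_cohort(params), params)
}
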