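---
title: "Externally validating colorectal cancer risk models with crcval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Externally validating colorectal cancer risk models with crcval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Risk prediction models for colorectal cancer (CRC) assign each person a
score — and sometimes an absolute 10-year risk — from demographic and
lifestyle inputs such as age, sex, body-mass index, smoking, alcohol
intake, diabetes and physical activity. Before such a model can guide
screening in a new population, it must be *externally validated* there:
its ability to rank future cases above non-cases (discrimination), its
agreement between predicted and observed risk (calibration), and its
usefulness for flagging a high-risk fraction of the population
(screening utility) all have to be measured on cohort data the model
never saw.

`crcval` packages that entire workflow. Risk scores are declarative
specification files rather than code; the statistics are exposed as
small, separately testable functions; and a synthetic cohort generator
with a known ground truth lets every stage run — and be checked for
parameter recovery — without access-controlled cohort data.

## The model registry

A specification file describes one published model: its functional form
(`logistic`, `cox`, or an integer `points` system), the cohort columns
it reads, per-variable contributions, the intercept or baseline
survival where the source article published one, an optional
points-to-absolute-risk table, the native prediction horizon, and the
sex the model was developed in. The engine evaluates

* logistic models as `risk = 1 / (1 + exp(-lp))`,
* Cox models as `risk = 1 - S0 ^ exp(lp)`, and
* point systems by summing integer contributions and looking the total
  up in the published risk table,

where `lp` is the coefficient-weighted covariate sum. Models that
published no absolute risk (a relative score only) yield `NA` risk, and
their calibration is — deliberately — not assessable, only their
discrimination.

Nine shipped specification files mirror the structure of well-known CRC
risk scores (Driver, Ma point and regression forms, Guo, Chen, Betes,
Aleksandrova, Imperiale, Hong): model type, variable lists, male-only
development for four of them, a 20-year native horizon for one, and
published absolute risk for five. Their *coefficient values are
synthetic placeholders* — plausible directions and magnitudes, marked
as such in each file's name and `provenance` field — because the
original coefficient tables are not redistributed here. Every numerical
property of the engine is therefore tested with fully synthetic
specifications, so correctness never rests on transcription. One
registry entry needed a judgement call: the second Ma model is described
inconsistently across sources (a Cox-style name, a logistic development
label); the shipped file declares it `logistic` with no intercept, i.e.
a relative score, which matches its absence from the set of models with
published absolute risk.

Two design choices worth knowing:

* **Aspirin.** Two models include aspirin use, which in the emulated
  cohort is observed only for people with a history of coronary heart
  disease. The spec files impute non-use where missing (the default
  policy); `run_validation(aspirin_policy = "drop_term")` removes the
  term instead, and the pipeline always reports a with/without paired
  contrast for aspirin-bearing models.
* **Proxies.** Inputs without an exact cohort equivalent (occupational
  sitting time, defecation frequency) are declared in the spec files
  against the canonical schema columns, so the mapping is configuration,
  not code.

## Follow-up and outcomes

Follow-up runs from entry to CRC, death from other causes, loss to
follow-up, or 10 years, whichever comes first. Outcome composites are
literal ICD-10 ranges: CRC C18–C20, colon C18, rectal C19–C20,
right-sided colon C18.0–C18.3, left-sided colon C18.5–C18.7. C18.4
(transverse colon) and C18.8/C18.9 count toward colon and CRC but
neither sided subset — the stated ranges are taken at face value rather
than extended. In site-specific analyses, a CRC event at another site is
*censored* at its event time rather than dropped, keeping risk sets
consistent with cohort time. Exclusions (prior intestinal cancer,
missing BMI) are logged per rule together with their overlap so the
retention arithmetic is exactly auditable.

For ROC analyses the outcome is binary: an event within 10 years is a
case and everyone else — including participants censored early — is a
control. This matches common validation practice and makes results
comparable across cohorts; the time-to-event information is used in the
Cox concordance sensitivity analysis instead.

## Discrimination

`empirical_auc()` computes the Mann–Whitney form of the AUC (ties
half-credit) with the DeLong variance from per-observation structural
components, evaluated via midranks in O(n log n). The paired
`delong_paired_test()` uses the DeLong covariance on identical
participants. The screening-policy comparator is a model whose only
input is `age >= 56` (the lower bound of the UK FIT screening range);
for a binary marker the AUC reduces to `(sensitivity + specificity)/2`
exactly, which the tests exploit.

Harrell's concordance is implemented exhaustively (vectorised over
events): a usable pair is an event versus a strictly longer-surviving
comparator, score ties credit 0.5, and pairs tied on time are unusable.
This follows the stated pair definition rather than delegating to
`survival::concordance`, whose tied-time conventions differ; the two
agree exactly on tie-free data, which the test suite verifies.

Top-fraction screening metrics flag the `ceiling(fraction * n)`
highest-scoring participants — "the top 10%" is read as *at least* 10%
— with ties broken deterministically by (score descending, id
ascending). Thresholds are computed on the whole cohort only; subgroup
analyses reuse overall scores rather than re-deriving thresholds within
strata, since screening policies are set population-wide.

Confidence intervals are 95% Wald on the AUC scale, truncated to
[0, 1]; DeLong p-values are two-sided and reported unadjusted (a
Bonferroni column is emitted alongside for transparency).

## Calibration and recalibration

Calibration is assessed for the five registry models that publish
absolute risk. Records are grouped by deciles of the predicted *score*
(for continuous-risk models this is identical to grouping on risk; for
point systems it is finer than the stepwise risk scale but induces the
same ordering). Heavily tied point totals can leave some decile groups
empty; empty groups are omitted and at least two occupied groups are
required. The per-group observed risk is by default the Kaplan–Meier
complement `1 - S(10)` — unbiased under censoring before the horizon —
with a crude proportion available by switch (the two coincide without
early censoring). The calibration line is ordinary least squares of
observed on expected over the group points (the group-point reading of
"split at deciles"), and recalibration applies `slope * risk +
intercept`, clamping to [0, 1] with the clamp count logged. The
20-year-horizon model's risks pass through the exponential horizon
conversion `1 - (1 - risk)^(10/20)` before calibration.

Recalibrating and refitting on the same data returns the identity line
(slope 1, intercept 0) up to floating point — an algebraic property of
OLS under affine transformation of the regressor that the tests assert,
and a useful self-check after any code change.

## The synthetic cohort generator

`cohort_params()` encodes the study conditions: ages 30–79 (truncated
normal, mean 51, sd 10.5), 59% female, ten regions (five urban, five
rural), and covariate marginals — smoking by sex, weekly drinking by
sex, BMI N(23.7, 3.3²), diabetes 5.9%, lognormal physical activity,
diet-frequency categories, 3% CHD history with aspirin observed only
there — chosen once as realistic order-of-magnitude values for a
middle-aged Chinese population cohort; they are configuration, not
estimates, and the package's conclusions never depend on their exact
values. Covariates are sampled independently given sex and region,
because published cohort descriptions give marginals, not a joint
distribution.

Outcomes follow a proportional-hazards model: CRC waiting time is
exponential with hazard `lambda0 * exp(lp)`, competing death (0.8%/yr)
and loss to follow-up (0.1%/yr) are independent exponentials, and
administrative censoring applies at 10 years; the earliest event wins
and CRC events draw an ICD-10 site code from a configurable split
(roughly half rectal, reflecting East-Asian site distributions).
`lambda0` is calibrated in closed form so the expected *crude* 10-year
CRC incidence — CRC as first event — equals the 0.58% target typical of
a middle-aged cohort of this age range. `true_risk()` exposes each
record's *net* (cause-specific) 10-year risk `1 - exp(-lambda0 *
exp(lp) * 10)`: that is the quantity a risk model predicts and the
estimand of the KM-based observed risk, which is what makes the
calibration-recovery tests clean (a model reporting `2 * true_risk`
must yield slope 0.5).

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: correlated covariates,
regional incidence gradients, age-dependent competing mortality,
reporting error in questionnaire variables, and non-exponential hazard
shapes. The generator demonstrates that the *machinery* recovers known
truths; it cannot certify any particular published model's performance
in a real population.

## Numerical choices

* Horizon conversion uses `-expm1((t2/t1) * log1p(-risk))`; risks close
  enough to 1 that `1 - risk` underflows are not representable in
  double precision under extreme horizon ratios, so validated use stays
  within clinically meaningful risks and 8–25-year horizons.
* Quantile grouping assigns ties to the lower group via minimum ranks;
  `ceiling(rank * G / n)` makes group sizes differ by at most one when
  values are distinct.
* Degenerate inputs fail loudly with classified errors (configuration,
  schema, degenerate-input, out-of-range) rather than returning NA
  silently; strata without both a case and a control are reported as
  undefined with the reason in the output table.
* The pipeline consumes no random numbers, so a run is reproducible
  from the cohort alone; the generator derives its outcome RNG stream
  from the single cohort seed.

## Problem sizes in the test suite

The suite exercises oracle equivalence on thousands of small random
instances (n ≤ 50 for AUC, n ≤ 200 for concordance), DeLong type-I
error with 2,000 null replicates at n = 500, calibration-slope recovery
on a 200,000-record cohort, binormal AUC recovery at 100,000, and full
pipeline determinism/completeness at 100,000 with all nine models, five
outcome composites and three subgroup schemes — sizes chosen so each
property is measured with comfortable Monte-Carlo margins while the
whole suite stays quick to run.

## Limitations

The shipped registry reproduces model *structure*, not published
coefficients; results from it characterise the pipeline, not the nine
original models. Calibration of relative-score models is out of reach
by construction. Time-dependent ROC, decision-curve analysis and
flexible (spline) calibration curves are out of scope; the emitted
tables are plot-ready inputs for standard graphics rather than finished
figures.
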