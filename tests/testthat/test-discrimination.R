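test_that("empirical AUC reproduces hand-computable cases", {
  expect_equal(empirical_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(empirical_auc(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  # ties get half credit: pairs (2,1)=1 (3,1)=1 (2,2)=0.5 (3,2)=1 -> 3.5/4
  expect_equal(empirical_auc(c(1, 2, 2, 3), c(0, 1, 0, 1))$auc, 0.875)
  expect_error(empirical_auc(1:4, c(1, 1, 1, 1)), "degenerate-input")
  expect_error(empirical_auc(c(1, Inf, 2), c(0, 1, 0)), "finite")
})

test_that("empirical AUC equals the exhaustive pair oracle with ties", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(1:8, n, replace = TRUE) + round(runif(n), 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(empirical_auc(scores, labels)$auc,
                 auc_oracle(scores, labels), tolerance = 1e-14)
  }
})

test_that("AUC symmetry and monotone-transform invariance hold", {
  set.seed(102)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    scores <- rnorm(n)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.3))
    a <- empirical_auc(scores, labels)
    expect_equal(a$auc + empirical_auc(-scores, labels)$auc, 1)
    expect_equal(empirical_auc(exp(2 * scores), labels)$auc, a$auc)
    expect_gte(a$variance, 0)
    expect_lte(a$ci_low, a$auc); expect_gte(a$ci_high, a$auc)
  }
})

test_that("AUC and DeLong variance agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(103)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    a <- empirical_auc(scores, labels)
    expect_equal(a$auc, as.numeric(pROC::auc(r)), tolerance = 1e-12)
    expect_equal(a$variance, pROC::var(r), tolerance = 1e-12)
  }
})

test_that("paired DeLong test matches pROC and degenerates correctly", {
  skip_if_not_installed("pROC")
  set.seed(104)
  for (i in 1:10) {
    n <- 80
    base <- rnorm(n)
    s1 <- base + rnorm(n)
    s2 <- 0.5 * base + rnorm(n)
    labels <- rbinom(n, 1, plogis(base))
    if (sum(labels) < 2 || sum(!labels) < 2) next
    ours <- delong_paired_test(s1, s2, labels)
    ref <- pROC::roc.test(pROC::roc(labels, s1, quiet = TRUE,
                                    direction = "<"),
                          pROC::roc(labels, s2, quiet = TRUE,
                                    direction = "<"),
                          method = "delong", paired = TRUE)
    expect_equal(ours$z, as.numeric(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
  s <- rnorm(40); l <- c(0, 1, rbinom(38, 1, 0.5))
  ident <- delong_paired_test(s, s, l)
  expect_equal(ident$z, 0)
  expect_equal(ident$p_two_sided, 1)
})

test_that("the age-threshold comparator equals (sens + spec) / 2", {
  # 10 cases (8 aged >= 56), 90 controls (30 aged >= 56)
  ages <- c(rep(60, 8), rep(50, 2), rep(60, 30), rep(50, 60))
  labels <- c(rep(1, 10), rep(0, 90))
  a <- age_threshold_comparator(ages, labels)
  expect_equal(a$auc, (0.8 + 60 / 90) / 2)
  # binary-marker identity on random instances
  set.seed(105)
  for (i in 1:50) {
    n <- sample(20:100, 1)
    ages <- sample(30:79, n, replace = TRUE)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.3))
    ind <- ages >= 56
    sens <- sum(ind & labels) / sum(labels)
    spec <- sum(!ind & !labels) / sum(!labels)
    expect_equal(age_threshold_comparator(ages, labels)$auc,
                 (sens + spec) / 2, tolerance = 1e-14)
  }
  # separation and null behaviour
  expect_equal(age_threshold_comparator(c(60, 60, 40, 40),
                                        c(1, 1, 0, 0))$auc, 1)
})

test_that("Harrell's C matches exhaustive enumeration and survival", {
  # worked 6-record example with one censored record
  t6 <- c(1, 2, 3, 4, 5, 6)
  e6 <- c(1, 1, 0, 1, 1, 1)
  s6 <- c(6, 5, 4, 3, 2, 2)
  expect_equal(concordance_cox(t6, e6, s6), concordance_oracle(t6, e6, s6))
  # perfect ranking without censoring
  expect_equal(concordance_cox(1:5, rep(1, 5), 5:1), 1)
  set.seed(106)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    t <- rexp(n) + 1e-3
    e <- rbinom(n, 1, 0.5)
    if (sum(e) == 0) e[1] <- 1
    s <- sample(1:6, n, replace = TRUE)
    expect_equal(concordance_cox(t, e, s), concordance_oracle(t, e, s),
                 tolerance = 1e-14)
    # cross-check against the survival package (untied times)
    cs <- survival::concordance(
      survival::Surv(t, e) ~ s, reverse = TRUE)$concordance
    expect_equal(concordance_cox(t, e, s), unname(cs), tolerance = 1e-12)
  }
  expect_error(concordance_cox(c(1, 1), c(0, 0), c(1, 2)), "usable")
  expect_error(concordance_cox(c(0, 1), c(1, 1), c(1, 2)), "positive")
})

test_that("random scores give chance concordance at scale", {
  set.seed(107)
  n <- 20000
  t <- rexp(n, 0.05)
  e <- rbinom(n, 1, 0.3)
  s <- rnorm(n)
  cc <- concordance_cox(pmin(t, 10), e * (t <= 10), s)
  expect_lt(abs(cc - 0.5), 0.02)
})

test_that("top-fraction screening metrics follow the 2x2 table", {
  # n=100, 10 cases; construct so exactly 3 cases are flagged in top 10%
  scores <- c(90 + 1:3, 50 + 1:7, 90 + 4:10, seq_len(83))
  labels <- c(rep(1, 10), rep(0, 90))
  tk <- topk_metrics(scores, labels, 0.10)
  expect_equal(tk$n_flagged, 10)
  expect_equal(tk$sensitivity, 0.3)
  expect_equal(tk$specificity, 83 / 90)
  expect_equal(tk$ppv, 0.3)
  expect_equal(tk$npv, 83 / 90)
  # all cases in the top fraction
  tk2 <- topk_metrics(c(10, 9, 1:8), c(1, 1, rep(0, 8)), 0.2)
  expect_equal(tk2$sensitivity, 1)
  expect_equal(tk2$ppv, 1)
  expect_equal(tk2$npv, 1)
  expect_error(topk_metrics(1:4, c(0, 1, 0, 1), 1.2))
})

test_that("tie-breaking in the top fraction is stable by id", {
  scores <- c(5, 5, 5, 1)
  labels <- c(1, 0, 0, 0)
  tk_a <- topk_metrics(scores, labels, 0.25, ids = 1:4)
  expect_equal(tk_a$sensitivity, 1)        # id 1 wins the tie
  tk_b <- topk_metrics(scores, labels, 0.25, ids = c(9, 1, 2, 3))
  expect_equal(tk_b$sensitivity, 0)        # id 9 loses the tie
})

test_that("subgroup discrimination stratifies and flags degenerate strata", {
  co <- toy_records(8, sex = rep(c("male", "female"), each = 4),
                    urban = rep(c(TRUE, FALSE), 4),
                    age = c(40, 60, 40, 60, 40, 60, 40, 60))
  scores <- c(4, 3, 2, 1, 4, 3, 2, 1)
  labels <- c(1, 0, 0, 1, 1, 0, 0, 1)
  res <- subgroup_discrimination(co, scores, labels, "sex")
  expect_equal(nrow(res), 2)
  expect_setequal(res$stratum, c("male", "female"))
  expect_true(all(res$note == ""))
  # an all-male cohort leaves the female stratum undefined, with reason
  co_m <- toy_records(4, sex = "male")
  res_m <- subgroup_discrimination(co_m, c(1, 2, 3, 4), c(0, 1, 0, 1),
                                   "sex")
  expect_true(is.na(res_m$auc[res_m$stratum == "female"]))
  expect_match(res_m$note[res_m$stratum == "female"], "degenerate")
  expect_error(subgroup_discrimination(co, scores, labels, "region"),
               "configuration error")
})

test_that("null markers show chance discrimination within each stratum", {
  set.seed(108)
  n <- 4000
  co <- toy_records(n,
                    sex = sample(c("male", "female"), n, TRUE),
                    urban = sample(c(TRUE, FALSE), n, TRUE),
                    age = runif(n, 30, 79))
  scores <- rnorm(n)
  labels <- rbinom(n, 1, 0.3)
  for (gr in c("sex", "urbanicity", "age")) {
    res <- subgroup_discrimination(co, scores, labels, gr)
    for (k in seq_len(nrow(res))) {
      expect_lt(abs(res$auc[k] - 0.5), 3 * sqrt(res$variance[k]))
    }
  }
})
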