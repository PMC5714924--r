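test_that("confusion tables count and transpose correctly", {
  pred <- data.frame(patient_id = c("A", "B", "C", "D"),
                     predicted = c("NSCLC", "NSCLC", "SCLC", "NSCLC"),
                     stringsAsFactors = FALSE)
  lab <- data.frame(patient_id = c("A", "B", "C", "D"),
                    subtype = c("NSCLC", "NSCLC", "SCLC", "SCLC"),
                    stringsAsFactors = FALSE)
  ct <- confusion_table(pred, lab)
  expect_equal(c(ct$tp, ct$fp, ct$fn, ct$tn), c(2, 1, 0, 1))

  swapped <- confusion_table(pred, lab, positive_class = "SCLC")
  expect_equal(c(swapped$tp, swapped$fp, swapped$fn, swapped$tn),
               c(ct$tn, ct$fn, ct$fp, ct$tp))

  expect_error(confusion_table(pred[1:3, ], lab),
               class = "casefindr_contract_error")
})

test_that("the validation table of a strong claims classifier reproduces its printed measures", {
  # 1,353-patient lung-cancer validation cohort, NSCLC positive
  da <- validate_table(tp = 1027, fp = 51, fn = 56, tn = 219)
  est <- function(m) da_estimate(da, m)
  expect_equal(round(100 * est("sensitivity"), 1), 94.8)
  expect_equal(round(100 * est("specificity"), 1), 81.1)
  expect_equal(round(100 * est("ppv"), 1), 95.3)
  expect_equal(round(100 * est("npv"), 1), 79.6)
  expect_equal(round(100 * est("accuracy"), 1), 92.1)
  expect_equal(round(est("dor"), 1), 78.8)
  expect_equal(round(est("auc"), 2), 0.88)
  m <- da$measures
  expect_true(all(m$ci_low <= m$estimate & m$estimate <= m$ci_high))
})

test_that("a worse-than-chance classifier's table yields its printed measures", {
  da <- validate_table(tp = 80, fp = 231, fn = 1003, tn = 39)
  est <- function(m) da_estimate(da, m)
  expect_equal(round(100 * est("sensitivity"), 1), 7.4)
  expect_equal(round(100 * est("specificity"), 1), 14.4)
  expect_equal(round(100 * est("ppv"), 1), 25.7)
  expect_equal(round(100 * est("npv"), 1), 3.7)
  expect_equal(round(100 * est("accuracy"), 1), 8.8)
  expect_equal(round(est("dor"), 2), 0.01)
})

test_that("perfect classifiers hit the boundaries and flag the undefined DOR", {
  da <- validate_table(tp = 10, fp = 0, fn = 0, tn = 10)
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy", "auc"))
    expect_equal(da_estimate(da, m), 1)
  expect_true(is.na(da_estimate(da, "dor")))
  expect_true("dor" %in% da$undefined)

  corrected <- diagnostic_odds_ratio(confusion_counts(5, 0, 0, 5), "haldane")
  expect_equal(corrected$dor, (5.5 * 5.5) / (0.5 * 0.5))  # = 121
  expect_true(corrected$correction_applied)
})

test_that("DOR equals the logistic-regression odds ratio on random tables", {
  set.seed(7)
  for (i in 1:20) {
    ct <- random_confusion_table()
    # oracle: OR from a saturated logistic fit of label on prediction
    y <- c(rep(1, ct$tp), rep(1, ct$fn), rep(0, ct$fp), rep(0, ct$tn))
    x <- c(rep(1, ct$tp), rep(0, ct$fn), rep(1, ct$fp), rep(0, ct$tn))
    or_glm <- exp(stats::coef(stats::glm(y ~ x, family = stats::binomial()))[["x"]])
    expect_equal(diagnostic_odds_ratio(ct)$dor, or_glm, tolerance = 1e-6)
  }
})

test_that("accuracy and DOR identities hold on random tables", {
  set.seed(123)
  for (i in 1:100) {
    ct <- random_confusion_table()
    da <- accuracy_measures(ct)
    est <- function(m) da_estimate(da, m)
    prev <- (ct$tp + ct$fn) / ct$total
    expect_equal(est("accuracy"),
                 est("sensitivity") * prev + est("specificity") * (1 - prev))
    expect_equal(est("dor"),
                 (est("sensitivity") / (1 - est("sensitivity"))) /
                   ((1 - est("specificity")) / est("specificity")))
    expect_equal(est("auc"), (est("sensitivity") + est("specificity")) / 2)
  }
})

test_that("Wilson intervals are sane at the boundaries", {
  ci0 <- casefindr:::wilson_ci(0, 50)
  ci1 <- casefindr:::wilson_ci(50, 50)
  expect_equal(ci0[1], 0)
  expect_gt(ci0[2], 0)
  expect_lt(ci1[1], 1)
  expect_equal(ci1[2], 1)
  # against prop.test's Wilson (no continuity correction)
  pt <- stats::prop.test(37, 60, correct = FALSE)$conf.int
  expect_equal(casefindr:::wilson_ci(37, 60), as.numeric(pt), tolerance = 1e-9)
})

test_that("cohort description summarises by subtype with closed percentages", {
  patients <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    index_date = as.Date("2015-01-01"),
    age_at_index = c(50, 70, 60, 62),
    gender = c("male", "female", "female", "male"),
    bmi = c(24, 28, 30, 22),
    dci_score = c(5, 9, 7, 8),
    cancer_stage = c("IV", "IV", "Limited", "IIIA"),
    insurance = "commercial",
    region = c("South", "South", "West", "Midwest"),
    stringsAsFactors = FALSE)
  labels <- data.frame(patient_id = c("A", "B", "C", "D"),
                       subtype = c("NSCLC", "NSCLC", "SCLC", "NSCLC"),
                       stringsAsFactors = FALSE)
  desc <- describe_cohort(patients, labels)
  expect_equal(desc$NSCLC[desc$feature == "n"], "3 (75.0)")
  expect_equal(desc$SCLC[desc$feature == "n"], "1 (25.0)")
  expect_equal(desc$NSCLC[desc$feature == "age"], "60.7 ± 10.1 (62.0)")
  stages <- desc[desc$feature == "cancer_stage", ]
  expect_setequal(stages$level, c("0", "IA", "IB", "IIA", "IIB", "IIIA",
                                  "IIIB", "IV", "Limited"))
  # in-subtype stage percentages sum to 100
  pct <- as.numeric(sub(".*\\((.*)\\)", "\\1", stages$NSCLC))
  expect_equal(sum(pct), 100)
})
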