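test_that("basic rates match hand arithmetic and handle empty classes", {
  ct <- confusion_table(tp = 50, fp = 0, tn = 50, fn = 0)
  r <- basic_rates(ct)
  expect_equal(r$accuracy, 1)
  expect_equal(r$oer, 0)

  ct <- confusion_table(tp = 40, fp = 10, tn = 30, fn = 20)
  r <- basic_rates(ct)
  expect_equal(r$sensitivity, 40 / 60)
  expect_equal(r$specificity, 30 / 40)
  expect_equal(r$precision, 40 / 50)
  expect_equal(r$accuracy + r$oer, 1)

  r <- basic_rates(confusion_table(tp = 0, fp = 5, tn = 5, fn = 0))
  expect_true(is.na(r$sensitivity))
  expect_match(attr(r$sensitivity, "reason"), "positive")
})

test_that("F-measure and g-means follow their definitions", {
  perfect <- confusion_table(tp = 10, fp = 0, tn = 10, fn = 0)
  fg <- f_and_gmeans(perfect)
  expect_equal(fg$f_measure, 1)
  expect_equal(fg$gmean1, 1)
  expect_equal(fg$gmean2, 1)

  ct <- confusion_table(tp = 40, fp = 10, tn = 30, fn = 20)
  fg <- f_and_gmeans(ct)
  se <- 40 / 60; pr <- 40 / 50; sp <- 30 / 40
  expect_equal(fg$f_measure, 2 * pr * se / (pr + se))
  expect_equal(fg$gmean1, sqrt(se * pr))
  expect_equal(fg$gmean2, sqrt(se * sp))

  # precision == sensitivity collapses F to that common value
  ct <- confusion_table(tp = 30, fp = 10, tn = 20, fn = 10)
  fg <- f_and_gmeans(ct)
  expect_equal(fg$f_measure, basic_rates(ct)$precision)
})

test_that("MCC hits its anchor values and symmetry", {
  expect_equal(mcc(confusion_table(50, 0, 50, 0)), 1)
  expect_equal(mcc(confusion_table(0, 10, 0, 10)), -1)
  expect_equal(mcc(confusion_table(25, 25, 25, 25)), 0)
  expect_true(is.na(mcc(confusion_table(5, 0, 0, 5))))
  # symmetric under simultaneous TP<->TN, FP<->FN swap
  set.seed(1)
  for (i in 1:50) {
    v <- sample(1:30, 4, replace = TRUE)
    a <- mcc(confusion_table(v[1], v[2], v[3], v[4]))
    b <- mcc(confusion_table(v[3], v[4], v[1], v[2]))
    expect_equal(a, b)
  }
})

test_that("closed-form AUC and balanced accuracy agree with direct averages", {
  expect_equal(auc_formula(confusion_table(10, 0, 10, 0)), 1)
  # sensitivity 0.8, specificity 0.6
  ct <- confusion_table(tp = 8, fn = 2, tn = 6, fp = 4)
  expect_equal(auc_formula(ct), 0.7)
  expect_equal(bacc(ct), 70)
  # everything predicted positive on balanced data
  ct <- confusion_table(tp = 10, fn = 0, tn = 0, fp = 10)
  expect_equal(auc_formula(ct), 0.5)
})

test_that("kappa matches the chance-corrected agreement anchors", {
  expect_equal(kappa_with_se(diag(c(7, 9)))$kappa, 1)
  # balanced two-class, accuracy 0.7, pe = 0.5 -> kappa 0.4
  m <- matrix(c(35, 15, 15, 35), 2, 2)
  k <- kappa_with_se(m)
  expect_equal(k$p0, 0.7)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.4)
  expect_true(k$above_chance)
  # simulated chance agreement: kappa ~ 0 within its CI
  set.seed(42)
  truth <- sample(1:2, 4000, replace = TRUE)
  pred <- sample(1:2, 4000, replace = TRUE)
  k <- kappa_with_se(table(truth, pred))
  expect_true(k$ci[1] < 0 && k$ci[2] > 0)
})

test_that("desirability rewards high stable performance", {
  v <- c(0.1, 0.2, 0.3)  # mean/sd ratio exactly 2
  d <- desirability(v, v, v, v, v, v)
  expect_equal(d$d1, 8)
  expect_equal(d$d2, 8)
  expect_equal(d$d, 2)
  # higher-mean / lower-spread set dominates
  good <- c(0.90, 0.92, 0.91, 0.93)
  poor <- c(0.60, 0.85, 0.55, 0.80)
  dg <- desirability(good, good, good, good, good, good)
  dp <- desirability(poor, poor, poor, poor, poor, poor)
  expect_gt(dg$d, dp$d)
  # constant vectors -> undefined signal
  const <- c(0.5, 0.5, 0.5)
  expect_true(is.na(desirability(const, good, good, good, good, good)$d))
})

test_that("metrics_report bundles consistent values", {
  ct <- confusion_table(tp = 40, fp = 10, tn = 30, fn = 20)
  rep <- metrics_report(ct)
  expect_equal(rep$bacc, 100 * rep$auc)
  expect_equal(rep$accuracy + rep$oer, 1)
  expect_length(rep$kappa_ci95, 2)
})
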