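test_that("regression metrics satisfy their defining identities", {
  m <- regression_metrics(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(m$r2, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$spearman_rho, 1)
  # mean predictor: R^2 = 0 by construction
  m2 <- regression_metrics(c(0, 1, 2), c(1, 1, 1))
  expect_equal(m2$r2, 0)
  expect_equal(m2$mse, 2 / 3)
  expect_equal(m2$rmse, sqrt(2 / 3))
  # property sweep: rmse^2 == mse and mae <= rmse on arbitrary vectors
  set.seed(31)
  for (i in 1:20) {
    y <- rnorm(50); p <- y + rnorm(50, 0, runif(1, 0.01, 2))
    mm <- regression_metrics(y, p)
    expect_equal(mm$rmse^2, mm$mse, tolerance = 1e-12)
    expect_lte(mm$mae, mm$rmse)
    expect_true(mm$spearman_rho >= -1 && mm$spearman_rho <= 1)
  }
  expect_error(regression_metrics(1:2, 1:2), "at least 3")
  expect_error(regression_metrics(c(1, 2, NA), c(1, 2, 3)), "non-finite")
})

test_that("negative R-squared arises when predictions underperform the mean", {
  set.seed(8)
  y <- rnorm(50)
  m <- regression_metrics(y, -2 * y)
  expect_lt(m$r2, 0)
})

test_that("confusion metrics are exact fractions of the stored counts", {
  r <- confusion_report_from_counts(tp = 34, fn = 6, tn = 65, fp = 7,
                                    positive = "high_risk")
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    m <- r[[nm]]
    expect_identical(m$value, m$num / m$den)
  }
  expect_equal(r$sensitivity$value, 34 / 40)
  expect_equal(r$accuracy$value, 99 / 112)
  # label-vector path agrees with the count path
  truth <- c(rep("high_risk", 40), rep("normal", 72))
  pred <- c(rep("high_risk", 34), rep("normal", 6), rep("high_risk", 7), rep("normal", 65))
  r2 <- confusion_report(truth, pred, positive = "high_risk",
                         labels = c("normal", "high_risk"))
  expect_identical(r2[c("tp", "fn", "tn", "fp")], r[c("tp", "fn", "tn", "fp")])
})

test_that("zero-denominator metrics are not-applicable, never zero", {
  r <- confusion_report(c("a", "a"), c("a", "a"), positive = "b",
                        labels = c("a", "b"))
  expect_true(is.na(r$sensitivity$value))
  expect_true(is.na(r$ppv$value))
  expect_equal(r$specificity$value, 1)
  expect_true(is.na(confusion_percentages(r)[["sensitivity"]]))
  expect_error(confusion_report(c("a", "c"), c("a", "a"), positive = "a",
                                labels = c("a", "b")), "outside the declared set")
})

test_that("stage accuracy reports numerator, denominator, and table", {
  truth <- c("I", "II", "II", "III")
  acc <- multiclass_accuracy(truth, truth)
  expect_equal(acc$accuracy$value, 1)
  acc2 <- multiclass_accuracy(c("I", "I"), c("II", "II"))
  expect_equal(acc2$accuracy$value, 0)
  expect_error(multiclass_accuracy(c("I", "V"), c("I", "I")), "declared set")
})

test_that("end-to-end evaluation keeps the discordance identity", {
  co <- fixture_noisy_cohort()
  ev <- run_full_evaluation(co, seed = 42, families = "random_forest")
  nh <- ev$normal_highrisk_report
  expect_identical(nrow(ev$discordant), nh$fp + nh$fn)
  expect_true(all(ev$discordant$group_pft != ev$discordant$group_model))
  # denominators: all validation subjects enter the COPD task; only subjects
  # predicted non-COPD with a non-COPD measured label enter the second task
  expect_equal(ev$copd_report$accuracy$den, ev$n_validation)
  expect_lte(nh$accuracy$den, ev$n_validation)
  expect_true(all(c("prm_whole_fsad_pct", "prm_whole_emph_pct") %in%
                    names(ev$discordant)))
})

test_that("a noiseless cohort evaluates with an empty discordant list", {
  co <- fixture_noiseless_cohort()
  ev <- run_full_evaluation(co, seed = 7, families = "random_forest")
  expect_identical(nrow(ev$discordant),
                   ev$normal_highrisk_report$fp + ev$normal_highrisk_report$fn)
  expect_lte(nrow(ev$discordant), 2)
  expect_gte(ev$regression$random_forest$fev1_pct$r2, 0.95)
})

test_that("evaluation reports round-trip through JSON unchanged", {
  co <- fixture_noisy_cohort()
  ev <- run_full_evaluation(co, seed = 42, families = "random_forest")
  path <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(ev, path)
  back <- read_evaluation_report(path)
  expect_equal(back$regression$random_forest$fev1_pct$r2,
               ev$regression$random_forest$fev1_pct$r2, tolerance = 1e-12)
  expect_equal(back$copd$tp, ev$copd_report$tp)
  expect_equal(back$normal_highrisk$percentages$accuracy,
               unname(confusion_percentages(ev$normal_highrisk_report)["accuracy"]))
  expect_equal(nrow(back$discordant), nrow(ev$discordant))
})
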