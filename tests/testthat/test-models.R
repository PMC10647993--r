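test_that("the 4:1 split is disjoint, exhaustive, and seed-stable", {
  co <- fixture_noisy_cohort()
  sp <- split_train_validation(co, seed = 5)
  expect_equal(nrow(sp$validation), round(nrow(co) / 5))
  expect_length(intersect(sp$indices$train, sp$indices$validation), 0)
  expect_setequal(c(sp$indices$train, sp$indices$validation), seq_len(nrow(co)))
  sp2 <- split_train_validation(co, seed = 5)
  expect_identical(sp$indices, sp2$indices)
  # explicit sizes override the ratio rule (published design: 494/121 on 615)
  co615 <- co[rep(seq_len(nrow(co)), length.out = 615), ]
  sp3 <- split_train_validation(co615, seed = 1, sizes = c(494, 121))
  expect_equal(nrow(sp3$train), 494)
  expect_equal(nrow(sp3$validation), 121)
  expect_error(split_train_validation(co, sizes = c(100, 100)), "sum to n")
  expect_error(split_train_validation(co[1:4, ]), "at least 5")
})

test_that("random forest learns a noiseless cohort and fails permuted targets", {
  co <- fixture_noiseless_cohort()
  sp <- split_train_validation(co, seed = 3)
  rf <- train_regressor(regressor_spec("random_forest", "fev1_pct", seed = 4), sp$train)
  m <- regression_metrics(sp$validation$fev1_pct, predict(rf, sp$validation))
  expect_gte(m$r2, 0.95)
  # permutation control: shuffling the target destroys the signal. A single
  # permutation can retain a chance correlation with the true target that a
  # flexible learner amplifies, so the control statistic is the mean over
  # repeated permutations.
  r2p <- vapply(1:3, function(i) {
    tr <- sp$train
    set.seed(100 + i)
    tr$fev1_pct <- sample(tr$fev1_pct)
    rfp <- train_regressor(regressor_spec("random_forest", "fev1_pct", seed = 5), tr)
    regression_metrics(sp$validation$fev1_pct, predict(rfp, sp$validation))$r2
  }, numeric(1))
  expect_lte(mean(r2p), 0.1)
  expect_true(all(r2p < 0.5))
})

test_that("fits and predictions are reproducible under a fixed seed", {
  co <- fixture_noisy_cohort()
  sp <- split_train_validation(co, seed = 2)
  a <- train_regressor(regressor_spec("random_forest", "fev1_fvc", seed = 7), sp$train)
  b <- train_regressor(regressor_spec("random_forest", "fev1_fvc", seed = 7), sp$train)
  expect_identical(predict(a, sp$validation), predict(b, sp$validation))
  # identical feature rows get identical predictions
  row2 <- sp$validation[c(1, 1), ]
  p <- predict(a, row2)
  expect_identical(p[1], p[2])
})

test_that("a single unpruned tree on the full sample memorizes its targets", {
  co <- fixture_noiseless_cohort()
  tr <- co[1:50, ]
  rf1 <- train_regressor(regressor_spec("random_forest", "fev1_pct", seed = 9,
    hyper = list(ntree = 1L, replace = FALSE, sampsize = 50L,
                 nodesize = 1L, mtry = 76L)), tr)
  expect_equal(predict(rf1, tr), tr$fev1_pct, tolerance = 1e-10)
})

test_that("predictions stay in the physiologic domain and flag bad columns", {
  co <- fixture_noisy_cohort()
  sp <- split_train_validation(co, seed = 2)
  rf <- train_regressor(regressor_spec("random_forest", "fev1_pct", seed = 7), sp$train)
  p <- predict(rf, sp$validation)
  expect_true(all(is.finite(p) & p > 0 & p <= 1.6))
  broken <- sp$validation[, setdiff(names(sp$validation), "age")]
  expect_error(predict(rf, broken), "age")
  expect_error(train_regressor(regressor_spec("random_forest", "fev1_pct"),
                               sp$train[, 1:10]), "feature columns missing")
})

test_that("raising fSAD% lowers the predicted FEV1%", {
  co <- fixture_noiseless_cohort()
  rf <- train_regressor(regressor_spec("random_forest", "fev1_pct", seed = 4), co)
  subj <- co[which.min(abs(co$prm_whole_fsad_pct - 10))[1], ]
  worse <- subj
  worse$prm_whole_fsad_pct <- worse$prm_whole_fsad_pct + 20
  expect_lt(predict(rf, worse), predict(rf, subj))
})

test_that("the MLP baseline trains on standardized inputs and predicts in-domain", {
  co <- fixture_noiseless_cohort()
  sp <- split_train_validation(co, seed = 3)
  mlp <- train_regressor(regressor_spec("mlp", "fev1_pct", seed = 6,
                                        hyper = list(size = 8L, maxit = 200L)), sp$train)
  p <- predict(mlp, sp$validation)
  expect_true(all(is.finite(p) & p > 0 & p <= 1.6))
  m <- regression_metrics(sp$validation$fev1_pct, p)
  expect_gt(m$r2, 0.5)
})

test_that("degenerate targets are handled explicitly", {
  co <- fixture_noisy_cohort()[1:40, ]
  co$fev1_pct <- 0.9
  # randomForest itself warns about regression on a constant response
  rf <- suppressWarnings(
    train_regressor(regressor_spec("random_forest", "fev1_pct", seed = 1), co))
  p <- predict(rf, co)
  expect_true(all(abs(p - 0.9) < 1e-9))
  expect_warning(m <- regression_metrics(co$fev1_pct, p), "zero variance")
  expect_true(is.na(m$r2))
  co$fev1_pct[1] <- NA
  expect_error(train_regressor(regressor_spec("random_forest", "fev1_pct"), co),
               "non-finite target")
})
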