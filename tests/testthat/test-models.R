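test_that("evaluation metrics match hand arithmetic and a brute-force oracle", {
  expect_equal(evaluate_predictions(c(10, 20), c(10, 20)),
               c(mae = 0, mape = 0, rmse = 0))
  m <- evaluate_predictions(c(10, 20), c(9, 22))
  expect_equal(m[["mae"]], 1.5)
  expect_equal(m[["mape"]], 10)
  expect_equal(m[["rmse"]], sqrt(2.5))
  set.seed(1)
  y <- runif(30, 5, 50); p <- y + rnorm(30)
  e <- y - p
  expect_equal(evaluate_predictions(y, p),
               c(mae = sum(abs(e)) / 30, mape = 100 * sum(abs(e) / y) / 30,
                 rmse = sqrt(sum(e^2) / 30)))
  expect_error(evaluate_predictions(c(0, 1), c(1, 1)), "MAPE undefined")
})

test_that("RMSE dominates MAE for any prediction vector", {
  for (s in 1:20) {
    set.seed(s)
    y <- runif(15, 1, 10); p <- y + rnorm(15)
    m <- evaluate_predictions(y, p)
    expect_gte(m[["rmse"]], m[["mae"]])
  }
})

test_that("baseline predictor and its relative index behave as defined", {
  expect_equal(baseline_predict(c(10, 20), 4), rep(15, 4))
  expect_error(baseline_predict(numeric(0), 2), "nonempty")
  b <- c(mae = 2, mape = 10, rmse = 3)
  expect_equal(compute_ri(b, b)$ri, 0)
  expect_error(compute_ri(c(mae = 0, mape = 1, rmse = 1), b), "strictly positive")
})

test_that("holdout split reproduces the 67/33 arithmetic and is seeded", {
  s <- holdout_split(92, seed = 1)
  expect_length(s$train, 61)
  expect_length(s$test, 31)
  expect_setequal(c(s$train, s$test), 1:92)
  s3 <- holdout_split(3, seed = 1)
  expect_length(s3$test, 1)
  expect_identical(holdout_split(50, seed = 9), holdout_split(50, seed = 9))
  expect_false(identical(holdout_split(50, seed = 9), holdout_split(50, seed = 10)))
})

test_that("individual model fitting is deterministic and learns linear signal", {
  ch <- planted_feature_cohort(n = 40, p = 5, n_informative = 2,
                               beta = c(3, -2), noise_sd = 0, seed = 1)
  lr <- fit_individual("lr", ch$X, ch$y, seed = 1)
  expect_lt(lr$cv_metrics[["mae"]], 1e-8)
  expect_error(fit_individual("mystery", ch$X, ch$y), "unknown model")

  rf1 <- fit_individual("rf", ch$X, ch$y, tuning_budget = 3, seed = 5)
  rf2 <- fit_individual("rf", ch$X, ch$y, tuning_budget = 3, seed = 5)
  expect_identical(rf1$cv_metrics, rf2$cv_metrics)
  for (m in c("svm", "adaboost", "xgb", "lgb")) {
    f1 <- fit_individual(m, ch$X, ch$y, tuning_budget = 2, seed = 3)
    f2 <- fit_individual(m, ch$X, ch$y, tuning_budget = 2, seed = 3)
    expect_identical(f1$cv_metrics, f2$cv_metrics)
    expect_true(all(is.finite(f1$cv_metrics)))
  }
})

test_that("boosted tree regression beats a single weak learner on planted signal", {
  ch <- planted_feature_cohort(n = 80, p = 4, n_informative = 2,
                               beta = c(4, 2), noise_sd = 0.3, seed = 2)
  fit <- adaboost_r2(ch$X, ch$y, n_rounds = 40, maxdepth = 3, seed = 1)
  pred <- predict(fit, ch$X)
  expect_gt(length(fit$members), 3)
  single <- predict(adaboost_r2(ch$X, ch$y, n_rounds = 1, maxdepth = 1, seed = 1), ch$X)
  expect_lt(mean(abs(ch$y - pred)), mean(abs(ch$y - single)))
  expect_identical(pred, predict(fit, ch$X))
})

test_that("shuffled-label control yields relative indices near zero", {
  ris <- sapply(1:10, function(s) {
    ch <- planted_feature_cohort(n = 60, p = 6, seed = 100 + s)
    set.seed(1000 + s)
    y_shuf <- sample(ch$y)  # no association left
    fit <- fit_individual("rf", ch$X, y_shuf, tuning_budget = 1, seed = s)
    folds <- fit$folds
    base <- rep(NA_real_, 60)
    for (f in unique(folds)) base[folds == f] <- mean(y_shuf[folds != f])
    compute_ri(evaluate_predictions(y_shuf, base),
               evaluate_predictions(y_shuf, fit$cv_predictions))$ri
  })
  expect_lt(abs(mean(ris)), 0.3)
})

test_that("stacking trains the second level on out-of-fold member predictions", {
  ch <- planted_feature_cohort(n = 50, p = 4, n_informative = 2,
                               beta = c(5, 3), noise_sd = 0.2, seed = 3)
  st <- fit_stacked(ch$X, ch$y, second_level = "linear", cv = 5, seed = 2)
  expect_equal(ncol(st$oof_matrix), 4)
  expect_identical(colnames(st$oof_matrix), c("rf", "adaboost", "xgb", "lgb"))
  expect_lt(st$cv_metrics[["mae"]], 2)  # strong signal: stack clearly learns
  preds <- st$predict(ch$X)
  expect_length(preds, 50)
  # determinism
  st2 <- fit_stacked(ch$X, ch$y, second_level = "linear", cv = 5, seed = 2)
  expect_identical(st$oof_matrix, st2$oof_matrix)
  expect_identical(st$cv_metrics, st2$cv_metrics)
})

test_that("average ensembles follow the RI-proportional weighting rule", {
  # equal RIs: WAE coincides with SAE
  pm <- cbind(a = c(1, 3, 5), b = c(2, 2, 2))
  expect_equal(average_ensemble_predict(pm, "WAE", member_ris = c(a = 1, b = 1)),
               average_ensemble_predict(pm, "SAE"))
  # RIs (1, 3) with member predictions (0, 4): 0.25*0 + 0.75*4 = 3
  expect_equal(average_ensemble_predict(cbind(0, 4), "WAE",
                                        member_ris = c(m1 = 1, m2 = 3)), 3)
  w <- ensemble_weights("WAE", c(a = 0.5, b = 1.2, c = 0.8, d = 0.1))
  expect_equal(sum(w), 1)
  expect_warning(w2 <- ensemble_weights("WAE", c(a = -0.2, b = 1)), "nonpositive")
  expect_equal(unname(w2), c(0, 1))
  expect_error(ensemble_weights("WAE", c(a = -1, b = 0)), "no member has positive RI")
})
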