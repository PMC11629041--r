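# Regression modelling: evaluation metrics, the training-mean baseline
# and relative index (RI), six individual regressors with seeded random
# hyperparameter search, two-level stacking with nested 5-fold CV, and
# the simple / RI-weighted average ensembles.

#' Regression evaluation metrics
#'
#' MAE = mean |e| (s), MAPE = 100 * mean(|e| / y_true) (%), and
#' RMSE = sqrt(mean(e^2)) (s).
#'
#' @param y_true,y_pred numeric vectors of equal length; `y_true` must be
#'   strictly positive (MAPE is undefined at zero).
#' @return Named numeric vector `c(mae, mape, rmse)`.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  assert_that(length(y_true) == length(y_pred) && length(y_true) >= 1,
              "y_true and y_pred must have equal positive length")
  assert_that(all(y_true > 0), "MAPE undefined: y_true contains nonpositive values")
  e <- y_true - y_pred
  c(mae = mean(abs(e)), mape = 100 * mean(abs(e) / y_true),
    rmse = sqrt(mean(e^2)))
}

#' Training-mean baseline predictor
#'
#' @param train_labels numeric training labels (nonempty).
#' @param n_test number of predictions to emit.
#' @return Constant vector equal to the training-label mean.
#' @export
baseline_predict <- function(train_labels, n_test) {
  assert_that(length(train_labels) >= 1, "train_labels must be nonempty")
  rep(mean(train_labels), n_test)
}

#' Relative index (RI)
#'
#' Sum over MAE, MAPE, RMSE of each metric's relative improvement over
#' the baseline: `ri = sum_m (baseline_m - model_m) / baseline_m`. The
#' baseline itself scores 0; positive values indicate overall improvement.
#'
#' @param baseline,model metric vectors as from [evaluate_predictions()]
#'   (baseline metrics must be strictly positive).
#' @return List with `ri` and `improvements` (per-metric terms).
#' @export
compute_ri <- function(baseline, model) {
  m <- c("mae", "mape", "rmse")
  assert_that(all(baseline[m] > 0), "baseline metrics must be strictly positive")
  imp <- (baseline[m] - model[m]) / baseline[m]
  list(ri = sum(imp), improvements = imp)
}

#' Random train/test holdout split
#'
#' @param n number of samples (>= 3).
#' @param test_fraction fraction held out (default 0.33; the test size is
#'   `ceiling(test_fraction * n)`, so 92 participants split 61/31).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(n, test_fraction = 0.33, seed = 1) {
  assert_that(n >= 3, "need at least 3 samples to split")
  n_test <- ceiling(test_fraction * n)
  assert_that(n_test >= 1 && n - n_test >= 2, "split leaves too few samples")
  idx <- with_seed(seed, sample.int(n))
  list(train = sort(idx[(n_test + 1):n]), test = sort(idx[seq_len(n_test)]))
}

# ---------------------------------------------------------------------------
# AdaBoost.R2 over rpart stumps/trees (weighted-median prediction).

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' AdaBoost.R2 regressor
#'
#' The classic boosting-for-regression algorithm: regression trees are
#' fitted to reweighted samples, each round's sample weights are updated
#' from the linear relative loss, and predictions are combined by the
#' weighted median of the member predictions.
#'
#' @param X numeric feature matrix.
#' @param y numeric labels.
#' @param n_rounds maximum boosting rounds.
#' @param maxdepth depth of the rpart base trees.
#' @param seed integer seed (rpart fits are deterministic; the seed
#'   covers any tie-breaking randomness).
#' @return An object of class `adaboost_r2` with a `predict` method.
#' @export
adaboost_r2 <- function(X, y, n_rounds = 50, maxdepth = 3, seed = 1) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(X)))
  df$y <- y
  w <- rep(1 / n, n)
  members <- list()
  betas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, xval = 0,
                               minsplit = max(4, floor(n / 10)))
  for (r in seq_len(n_rounds)) {
    fit <- with_seed(seed + r, rpart::rpart(y ~ ., df, weights = w * n, control = ctrl))
    pred <- stats::predict(fit, df)
    err <- abs(y - pred)
    emax <- max(err)
    if (emax == 0) {  # perfect member: keep it with full confidence
      members[[length(members) + 1]] <- fit
      betas <- c(betas, 1e-10)
      break
    }
    loss <- err / emax
    lbar <- sum(w * loss)
    if (lbar >= 0.5) break
    beta <- lbar / (1 - lbar)
    members[[length(members) + 1]] <- fit
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  if (!length(members)) {  # single weak member fallback
    members <- list(with_seed(seed, rpart::rpart(y ~ ., df, control = ctrl)))
    betas <- 1
  }
  structure(list(members = members, log_inv_beta = log(1 / betas),
                 p = ncol(X)), class = "adaboost_r2")
}

#' @export
predict.adaboost_r2 <- function(object, newdata, ...) {
  newdata <- as_feature_matrix(newdata)
  df <- as.data.frame(newdata)
  names(df) <- paste0("x", seq_len(object$p))
  preds <- vapply(object$members, function(m) stats::predict(m, df),
                  numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  apply(preds, 1, weighted_median, w = object$log_inv_beta)
}

# ---------------------------------------------------------------------------
# Model registry: fit and predict closures + hyperparameter samplers.

MODEL_NAMES <- c("lr", "svm", "rf", "adaboost", "xgb", "lgb")
TREE_MODELS <- c("rf", "adaboost", "xgb", "lgb")

xgb_fit <- function(X, y, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = c(params, list(nthread = 1, seed = seed)),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

# Draw one hyperparameter configuration for `name` (assumes an active
# seeded RNG context).
sample_config <- function(name, p) {
  switch(name,
    lr = list(),
    svm = list(cost = 2^stats::runif(1, -2, 6),
               gamma = 2^stats::runif(1, -7, 1) / p,
               epsilon = stats::runif(1, 0.01, 0.3)),
    rf = list(ntree = sample(c(200, 300, 400), 1),
              mtry = sample.int(p, 1),
              nodesize = sample(c(1, 3, 5), 1)),
    adaboost = list(n_rounds = sample(20:60, 1),
                    maxdepth = sample(2:4, 1)),
    xgb = list(nrounds = sample(c(50, 100, 200), 1),
               eta = stats::runif(1, 0.03, 0.3),
               max_depth = sample(2:5, 1),
               subsample = stats::runif(1, 0.6, 1),
               colsample_bytree = stats::runif(1, 0.6, 1),
               min_child_weight = sample(1:5, 1)),
    lgb = list(nrounds = sample(c(50, 100, 200), 1),
               eta = stats::runif(1, 0.03, 0.3),
               max_leaves = sample(c(7, 15, 31), 1),
               subsample = stats::runif(1, 0.6, 1),
               colsample_bytree = stats::runif(1, 0.6, 1),
               min_child_weight = sample(1:5, 1))
  )
}

default_config <- function(name) {
  switch(name,
    lr = list(),
    svm = list(cost = 4, gamma = NULL, epsilon = 0.1),
    rf = list(ntree = 300, mtry = NULL, nodesize = 3),
    adaboost = list(n_rounds = 40, maxdepth = 3),
    xgb = list(nrounds = 100, eta = 0.1, max_depth = 3, subsample = 0.9,
               colsample_bytree = 0.9, min_child_weight = 2),
    lgb = list(nrounds = 100, eta = 0.1, max_leaves = 15, subsample = 0.9,
               colsample_bytree = 0.9, min_child_weight = 2)
  )
}

# Fit one model with a fixed configuration; returns an object with a
# predict(newX) closure.
fit_config <- function(name, X, y, config, seed) {
  X <- as_feature_matrix(X)
  p <- ncol(X)
  predictor <- switch(name,
    lr = {
      fit <- stats::lm.fit(cbind(1, X), y)
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      function(newX) as.numeric(cbind(1, newX) %*% coefs)
    },
    svm = {
      gamma <- config$gamma %||% (1 / p)
      fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                        cost = config$cost %||% 4, gamma = gamma,
                        epsilon = config$epsilon %||% 0.1, scale = TRUE)
      function(newX) as.numeric(stats::predict(fit, newX))
    },
    rf = {
      mtry <- config$mtry %||% max(1, floor(p / 3))
      fit <- with_seed(seed, randomForest::randomForest(
        X, y, ntree = config$ntree %||% 300, mtry = min(mtry, p),
        nodesize = config$nodesize %||% 3))
      function(newX) as.numeric(stats::predict(fit, newX))
    },
    adaboost = {
      fit <- adaboost_r2(X, y, n_rounds = config$n_rounds %||% 40,
                         maxdepth = config$maxdepth %||% 3, seed = seed)
      function(newX) stats::predict(fit, newX)
    },
    xgb = {
      fit <- xgb_fit(X, y, params = list(
        eta = config$eta, max_depth = config$max_depth,
        subsample = config$subsample, colsample_bytree = config$colsample_bytree,
        min_child_weight = config$min_child_weight, objective = "reg:squarederror"
      ), nrounds = config$nrounds, seed = seed)
      function(newX) as.numeric(stats::predict(fit, as_feature_matrix(newX)))
    },
    lgb = {
      # leaf-wise histogram gradient booster (LightGBM-style growth)
      fit <- xgb_fit(X, y, params = list(
        eta = config$eta, max_depth = 0, max_leaves = config$max_leaves,
        grow_policy = "lossguide", tree_method = "hist",
        subsample = config$subsample, colsample_bytree = config$colsample_bytree,
        min_child_weight = config$min_child_weight, objective = "reg:squarederror"
      ), nrounds = config$nrounds, seed = seed)
      function(newX) as.numeric(stats::predict(fit, as_feature_matrix(newX)))
    },
    stopf("unknown model name '%s'", name)
  )
  list(name = name, config = config, predict = predictor)
}

cv_predictions <- function(name, X, y, config, folds, seed) {
  preds <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- fit_config(name, X[tr, , drop = FALSE], y[tr], config, seed + f)
    preds[!tr] <- fit$predict(X[!tr, , drop = FALSE])
  }
  preds
}

cv_fold_metrics <- function(y, preds, folds) {
  per_fold <- t(vapply(sort(unique(folds)), function(f) {
    evaluate_predictions(y[folds == f], preds[folds == f])
  }, c(mae = 0, mape = 0, rmse = 0)))
  colMeans(per_fold)
}

#' Fit and tune one individual regressor
#'
#' Seeded random hyperparameter search within the documented spaces,
#' scored by 5-fold cross-validated MAE on shared folds; the reported
#' metrics are the fold-averaged MAE/MAPE/RMSE of the winning
#' configuration, and the returned model is refitted on all data.
#'
#' @param model_name one of `"lr"`, `"svm"`, `"rf"`, `"adaboost"`,
#'   `"xgb"`, `"lgb"` (`lgb` is the leaf-wise histogram gradient
#'   booster).
#' @param X numeric feature matrix (>= 10 rows).
#' @param y numeric labels.
#' @param tuning_budget number of random configurations tried (ignored
#'   for `lr`).
#' @param cv number of CV folds.
#' @param seed integer seed controlling folds, search, and fits.
#' @return List: `model_name`, `config`, `cv_metrics`, `cv_predictions`
#'   (out-of-fold), `folds`, and `predict(newX)`.
#' @export
fit_individual <- function(model_name, X, y, tuning_budget = 10, cv = 5, seed = 1) {
  assert_that(model_name %in% MODEL_NAMES,
              "unknown model name '%s'", model_name)
  X <- as_feature_matrix(X)
  assert_that(nrow(X) >= 10, "need at least 10 training rows")
  folds <- make_folds(nrow(X), cv, seed)
  configs <- if (model_name == "lr") list(list()) else c(
    list(default_config(model_name)),
    with_seed(seed + 1000L, lapply(seq_len(max(tuning_budget - 1, 0)),
                                   function(i) sample_config(model_name, ncol(X))))
  )
  best <- NULL
  for (cf in configs) {
    preds <- cv_predictions(model_name, X, y, cf, folds, seed)
    mae <- mean(abs(y - preds))
    if (is.null(best) || mae < best$mae) {
      best <- list(config = cf, preds = preds, mae = mae)
    }
  }
  final <- fit_config(model_name, X, y, best$config, seed)
  list(model_name = model_name,
       config = best$config,
       cv_metrics = cv_fold_metrics(y, best$preds, folds),
       cv_predictions = best$preds,
       folds = folds,
       predict = final$predict)
}

#' Two-level stacked regressor with nested 5-fold CV
#'
#' First level: the four tree-based members (RF, AdaBoost, leaf-wise and
#' depth-wise gradient boosters). Within each outer training split, inner
#' 5-fold out-of-fold member predictions form the n x 4 second-level
#' design matrix; the second-level model (linear or RBF-kernel SVM) is
#' trained on it, and the outer validation fold — never seen by any
#' member — scores the stack.
#'
#' @param X numeric feature matrix.
#' @param y numeric labels.
#' @param second_level `"linear"` or `"svm"`.
#' @param members member model names (default the four tree models).
#' @param member_configs optional named list of fixed member
#'   configurations (defaults per member otherwise).
#' @param cv folds for both nesting levels.
#' @param seed integer seed.
#' @return List: `cv_metrics`, `cv_predictions` (outer out-of-fold),
#'   `folds`, `oof_matrix` (inner out-of-fold member predictions on the
#'   full data), `members`, and `predict(newX)`.
#' @export
fit_stacked <- function(X, y, second_level = c("linear", "svm"),
                        members = TREE_MODELS, member_configs = NULL,
                        cv = 5, seed = 1) {
  second_level <- match.arg(second_level)
  X <- as_feature_matrix(X)
  n <- nrow(X)
  folds <- make_folds(n, cv, seed)
  if (min(table(folds)) < 2) stopf("fold with fewer than 2 samples")
  configs <- lapply(stats::setNames(members, members), function(m) {
    member_configs[[m]] %||% default_config(m)
  })

  oof_members <- function(Xs, ys, inner_seed) {
    inner_folds <- make_folds(nrow(Xs), cv, inner_seed)
    mat <- vapply(members, function(m) {
      cv_predictions(m, Xs, ys, configs[[m]], inner_folds, inner_seed)
    }, numeric(nrow(Xs)))
    matrix(mat, nrow = nrow(Xs), dimnames = list(NULL, members))
  }
  fit_second <- function(Z, ys) {
    if (second_level == "linear") {
      fit <- stats::lm.fit(cbind(1, Z), ys)
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      function(Znew) as.numeric(cbind(1, Znew) %*% coefs)
    } else {
      fit <- e1071::svm(Z, ys, type = "eps-regression", kernel = "radial")
      function(Znew) as.numeric(stats::predict(fit, Znew))
    }
  }
  member_matrix <- function(fits, newX) {
    matrix(vapply(fits, function(f) f$predict(newX), numeric(nrow(newX))),
           nrow = nrow(newX), dimnames = list(NULL, members))
  }

  outer_preds <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    Ztr <- oof_members(X[tr, , drop = FALSE], y[tr], seed + 10L * f)
    second <- fit_second(Ztr, y[tr])
    fits <- lapply(members, function(m) {
      fit_config(m, X[tr, , drop = FALSE], y[tr], configs[[m]], seed + 10L * f)
    })
    outer_preds[!tr] <- second(member_matrix(fits, X[!tr, , drop = FALSE]))
  }

  oof_full <- oof_members(X, y, seed)
  second_full <- fit_second(oof_full, y)
  fits_full <- lapply(stats::setNames(members, members), function(m) {
    fit_config(m, X, y, configs[[m]], seed)
  })

  list(model_name = paste0("stack_", second_level),
       second_level = second_level,
       members = members,
       cv_metrics = cv_fold_metrics(y, outer_preds, folds),
       cv_predictions = outer_preds,
       folds = folds,
       oof_matrix = oof_full,
       predict = function(newX) {
         second_full(member_matrix(fits_full, as_feature_matrix(newX)))
       })
}

#' RI-proportional ensemble weights
#'
#' SAE weights members equally; WAE weights them by the proportion of
#' their relative-index values. Members with nonpositive RI are excluded
#' from WAE (a weight proportional to a nonpositive improvement is
#' undefined); it is an error if no member has positive RI.
#'
#' @param mode `"SAE"` or `"WAE"`.
#' @param member_ris named numeric RI values (required for WAE).
#' @param n_members member count (for SAE when `member_ris` is absent).
#' @return Named weight vector summing to 1 (excluded members weight 0).
#' @export
ensemble_weights <- function(mode = c("SAE", "WAE"), member_ris = NULL,
                             n_members = length(member_ris)) {
  mode <- match.arg(mode)
  if (mode == "SAE") {
    w <- rep(1 / n_members, n_members)
    if (!is.null(member_ris)) names(w) <- names(member_ris)
    return(w)
  }
  assert_that(!is.null(member_ris), "WAE requires member RI values")
  w <- pmax(member_ris, 0)
  assert_that(any(w > 0), "WAE undefined: no member has positive RI")
  if (any(member_ris <= 0)) {
    warning("excluding member(s) with nonpositive RI from WAE", call. = FALSE)
  }
  w / sum(w)
}

#' Average-ensemble prediction from member predictions
#'
#' @param pred_matrix n x m matrix of member predictions.
#' @param mode `"SAE"` or `"WAE"`.
#' @param member_ris RI values matching the columns (WAE).
#' @return Numeric prediction vector.
#' @export
average_ensemble_predict <- function(pred_matrix, mode = c("SAE", "WAE"),
                                     member_ris = NULL) {
  mode <- match.arg(mode)
  pred_matrix <- as.matrix(pred_matrix)
  w <- ensemble_weights(mode, member_ris, n_members = ncol(pred_matrix))
  as.numeric(pred_matrix %*% w)
}

#' Fit a simple or RI-weighted average ensemble
#'
#' @param member_fits named list of fitted members (as from
#'   [fit_individual()]).
#' @param mode `"SAE"` or `"WAE"`.
#' @param member_ris named RI values per member (WAE).
#' @param y training labels; when supplied, fold-averaged CV metrics of
#'   the combined out-of-fold predictions are reported.
#' @return List with `weights`, `cv_metrics` (when `y` is given), and
#'   `predict(newX)`.
#' @export
fit_average_ensemble <- function(member_fits, mode = c("SAE", "WAE"),
                                 member_ris = NULL, y = NULL) {
  mode <- match.arg(mode)
  w <- ensemble_weights(mode, member_ris, n_members = length(member_fits))
  oof <- vapply(member_fits, function(f) f$cv_predictions,
                numeric(length(member_fits[[1]]$cv_predictions)))
  cv_preds <- as.numeric(oof %*% w)
  list(model_name = mode, weights = w,
       cv_predictions = cv_preds,
       cv_metrics = if (!is.null(y)) cv_fold_metrics(y, cv_preds, member_fits[[1]]$folds),
       folds = member_fits[[1]]$folds,
       predict = function(newX) {
         pm <- vapply(member_fits, function(f) f$predict(newX),
                      numeric(nrow(as_feature_matrix(newX))))
         as.numeric(matrix(pm, ncol = length(member_fits)) %*% w)
       })
}
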