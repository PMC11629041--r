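# End-to-end pipeline orchestration: simulate -> segment -> featurize ->
# select -> train -> report, with one explicit seed per stochastic stage.

#' Pipeline run configuration
#'
#' @param task `"fpwt40"` or `"tugt"` — which functional-test time to
#'   predict.
#' @param n_participants synthetic cohort size.
#' @param seed master seed; per-stage seeds (cohort, split, selection,
#'   models) are derived from it so stages are independently
#'   reproducible.
#' @param test_fraction holdout fraction (default 0.33).
#' @param segmentation_threshold detection threshold in %BW (default: 5%
#'   of each recording's maximum total VGRF).
#' @param spearman_threshold Spearman filter threshold.
#' @param mrmr_k mRMR subset size (default: training-set size).
#' @param wrapper `"sbfs"`, `"sffs"`, or `"none"`.
#' @param wrapper_max_size optional cap on wrapper subset size.
#' @param models individual model names to train.
#' @param include_stack,include_average train the stacked and averaged
#'   ensembles (the four tree members must be among `models`).
#' @param tuning_budget random-search draws per tuned model.
#' @param cv CV folds throughout.
#' @param cohort optional pre-generated cohort (skips simulation).
#' @param feature_table optional precomputed feature table (skips
#'   simulation and extraction).
#' @param labels labels data.frame matching `feature_table` (required
#'   with it).
#' @param output_dir optional directory for CSV/JSON artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(task = c("fpwt40", "tugt"),
                            n_participants = 92,
                            seed = 7,
                            test_fraction = 0.33,
                            segmentation_threshold = NULL,
                            spearman_threshold = 0.2,
                            mrmr_k = NULL,
                            wrapper = "sbfs",
                            wrapper_max_size = 15,
                            models = MODEL_NAMES,
                            include_stack = TRUE,
                            include_average = TRUE,
                            tuning_budget = 8,
                            cv = 5,
                            cohort = NULL,
                            feature_table = NULL,
                            labels = NULL,
                            output_dir = NULL) {
  task <- match.arg(task)
  structure(as.list(environment()), class = "pipeline_config")
}

model_report_row <- function(name, cv_metrics, cv_ri, test_metrics, test_ri) {
  data.frame(model = name,
             cv_mae = cv_metrics[["mae"]], cv_mape = cv_metrics[["mape"]],
             cv_rmse = cv_metrics[["rmse"]], cv_ri = cv_ri,
             test_mae = test_metrics[["mae"]], test_mape = test_metrics[["mape"]],
             test_rmse = test_metrics[["rmse"]], test_ri = test_ri)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, extracts the 384-column feature
#' table, performs the 67/33 holdout split, runs the selection cascade
#' on the training split, trains the requested individual models,
#' stacked models, and SAE/WAE ensembles, and evaluates everything
#' against the training-mean baseline on both the training CV and the
#' holdout test set.
#'
#' @param config a [pipeline_config()].
#' @return A list report: `task`, `n_train` / `n_test`, `selection`
#'   (the trace), `models` (data.frame of per-model CV and test
#'   MAE/MAPE/RMSE/RI), `baseline` (metrics), `weights` (WAE weights,
#'   when fitted), `stage_counts` (log of per-stage sizes), and `split`.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  cfg <- config
  seeds <- list(cohort = cfg$seed, split = cfg$seed + 1L,
                selection = cfg$seed + 2L, models = cfg$seed + 3L)
  stage_counts <- list()

  # --- data ---------------------------------------------------------------
  if (is.null(cfg$feature_table)) {
    cohort <- cfg$cohort %||% generate_cohort(
      cohort_spec(n_participants = cfg$n_participants, seed = seeds$cohort))
    features <- build_feature_table(cohort, threshold = cfg$segmentation_threshold)
    labels <- cohort$labels
  } else {
    features <- cfg$feature_table
    labels <- cfg$labels
    assert_that(!is.null(labels), "labels are required with a precomputed feature_table")
  }
  label_col <- if (cfg$task == "fpwt40") "fpwt40_s" else "tugt_s"
  y <- labels[[label_col]][match(features$participant_id, labels$participant_id)]
  X <- as_feature_matrix(features[, setdiff(names(features), "participant_id")])
  stage_counts$participants <- nrow(X)
  stage_counts$features_extracted <- ncol(X)

  # --- split & imputation --------------------------------------------------
  split <- holdout_split(nrow(X), cfg$test_fraction, seeds$split)
  imp <- impute_train_means(X[split$train, , drop = FALSE],
                            X[split$test, , drop = FALSE])
  X_train <- imp$train; X_test <- imp$test
  y_train <- y[split$train]; y_test <- y[split$test]
  stage_counts$n_train <- length(split$train)
  stage_counts$n_test <- length(split$test)

  # --- selection (training split only) -------------------------------------
  trace <- run_selection_cascade(
    X_train, y_train,
    spearman_threshold = cfg$spearman_threshold,
    k = cfg$mrmr_k %||% nrow(X_train),
    wrapper = cfg$wrapper,
    base_model = rf_predictor(ntree = 100, seed = seeds$selection),
    cv = cfg$cv, seed = seeds$selection,
    max_size = cfg$wrapper_max_size
  )
  sel <- trace$final
  stage_counts$features_after_spearman <- length(trace$stages$spearman$retained)
  stage_counts$features_after_mrmr <- length(trace$stages$mrmr$retained)
  stage_counts$features_selected <- length(sel)
  Xs_train <- X_train[, sel, drop = FALSE]
  Xs_test <- X_test[, sel, drop = FALSE]

  # --- baseline -------------------------------------------------------------
  folds <- make_folds(length(y_train), cfg$cv, seeds$models)
  base_cv_preds <- rep(NA_real_, length(y_train))
  for (f in sort(unique(folds))) {
    base_cv_preds[folds == f] <- baseline_predict(y_train[folds != f], sum(folds == f))
  }
  baseline_cv <- cv_fold_metrics(y_train, base_cv_preds, folds)
  baseline_test <- evaluate_predictions(
    y_test, baseline_predict(y_train, length(y_test)))

  rows <- list(model_report_row("baseline", baseline_cv, 0, baseline_test, 0))
  ri_of <- function(metrics, baseline) compute_ri(baseline, metrics)$ri

  # --- individual models ----------------------------------------------------
  fits <- list()
  for (m in cfg$models) {
    fit <- fit_individual(m, Xs_train, y_train, tuning_budget = cfg$tuning_budget,
                          cv = cfg$cv, seed = seeds$models)
    fits[[m]] <- fit
    test_metrics <- evaluate_predictions(y_test, fit$predict(Xs_test))
    rows[[length(rows) + 1]] <- model_report_row(
      m, fit$cv_metrics, ri_of(fit$cv_metrics, baseline_cv),
      test_metrics, ri_of(test_metrics, baseline_test))
  }

  # --- stacked models -------------------------------------------------------
  if (cfg$include_stack && all(TREE_MODELS %in% names(fits))) {
    member_configs <- lapply(fits[TREE_MODELS], `[[`, "config")
    for (sl in c("linear", "svm")) {
      st <- fit_stacked(Xs_train, y_train, second_level = sl,
                        member_configs = member_configs,
                        cv = cfg$cv, seed = seeds$models)
      test_metrics <- evaluate_predictions(y_test, st$predict(Xs_test))
      rows[[length(rows) + 1]] <- model_report_row(
        st$model_name, st$cv_metrics, ri_of(st$cv_metrics, baseline_cv),
        test_metrics, ri_of(test_metrics, baseline_test))
    }
  }

  # --- average ensembles ----------------------------------------------------
  weights <- NULL
  if (cfg$include_average && all(TREE_MODELS %in% names(fits))) {
    member_ris <- vapply(fits[TREE_MODELS],
                         function(f) ri_of(f$cv_metrics, baseline_cv), 0)
    for (mode in c("SAE", "WAE")) {
      if (mode == "WAE" && !any(member_ris > 0)) next
      ens <- fit_average_ensemble(fits[TREE_MODELS], mode,
                                  member_ris = member_ris, y = y_train)
      if (mode == "WAE") weights <- ens$weights
      test_metrics <- evaluate_predictions(y_test, ens$predict(Xs_test))
      rows[[length(rows) + 1]] <- model_report_row(
        mode, ens$cv_metrics, ri_of(ens$cv_metrics, baseline_cv),
        test_metrics, ri_of(test_metrics, baseline_test))
    }
  }

  report <- list(
    task = cfg$task,
    seed = cfg$seed,
    n_train = length(split$train),
    n_test = length(split$test),
    split = split,
    baseline = list(cv = baseline_cv, test = baseline_test),
    selection = trace,
    selected_features = sel,
    models = do.call(rbind, rows),
    weights = weights,
    stage_counts = stage_counts
  )

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(cfg$output_dir, "feature_table.csv"),
                     row.names = FALSE)
    write_selection_trace(trace, file.path(cfg$output_dir,
                                           sprintf("selection_%s.json", cfg$task)))
    utils::write.csv(report$models,
                     file.path(cfg$output_dir, sprintf("models_%s.csv", cfg$task)),
                     row.names = FALSE)
    jsonlite::write_json(
      list(task = cfg$task, stage_counts = stage_counts,
           models = report$models, wae_weights = weights),
      file.path(cfg$output_dir, sprintf("report_%s.json", cfg$task)),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
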