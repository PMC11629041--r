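#!/usr/bin/env Rscript
# Train and evaluate the full model roster per task: the six individual
# regressors, both stacked models (linear / SVM second level), and the
# simple and RI-weighted average ensembles of the four tree members.
# Reports training-set cross-validation and holdout metrics with the
# relative index against the training-mean baseline.

suppressMessages(library(plantargait))

features <- read.csv("results/feature_table.csv", check.names = FALSE)
labels <- read.csv("results/labels.csv")

for (task in c("fpwt40", "tugt")) {
  cfg <- pipeline_config(
    task = task, seed = 8, wrapper = if (task == "fpwt40") "sbfs" else "sffs",
    mrmr_k = 30, wrapper_max_size = 15, tuning_budget = 8,
    feature_table = features, labels = labels, output_dir = "results"
  )
  t0 <- Sys.time()
  rep <- run_pipeline(cfg)
  cat(sprintf("\n[%s] %d train / %d test, %d selected features, %.0f s\n",
              task, rep$n_train, rep$n_test, length(rep$selected_features),
              as.numeric(Sys.time() - t0, units = "secs")))
  print(rep$models[, c("model", "cv_mae", "cv_mape", "cv_rmse", "cv_ri",
                       "test_mae", "test_ri")], digits = 3)
  if (!is.null(rep$weights)) {
    cat("WAE weights: ", paste(sprintf("%s=%.3f", names(rep$weights),
                                       rep$weights), collapse = ", "), "\n")
  }
}
cat("\nWrote models_<task>.csv and report_<task>.json under results/\n")
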