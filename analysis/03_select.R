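#!/usr/bin/env Rscript
# Stepwise feature selection per task on the training split of the 67/33
# holdout: Spearman filter (|rho| >= 0.2), mRMR ranking, and the
# sequential floating wrapper (backward for the walk test, forward for
# the up-and-go test, mirroring which direction won per task).

suppressMessages(library(plantargait))

features <- read.csv("results/feature_table.csv", check.names = FALSE)
labels <- read.csv("results/labels.csv")
X <- as.matrix(features[, setdiff(names(features), "participant_id")])
split <- holdout_split(nrow(X), test_fraction = 0.33, seed = 8)
cat(sprintf("Holdout split: %d train / %d test\n",
            length(split$train), length(split$test)))

for (task in c("fpwt40", "tugt")) {
  y <- labels[[paste0(task, "_s")]]
  Xtr <- plantargait:::impute_train_means(X[split$train, ])
  trace <- run_selection_cascade(
    Xtr, y[split$train],
    k = 30, wrapper = if (task == "fpwt40") "sbfs" else "sffs",
    base_model = rf_predictor(ntree = 100, seed = 1),
    cv = 5, seed = 10, max_size = 15
  )
  counts <- c(spearman = length(trace$stages$spearman$retained),
              mrmr = length(trace$stages$mrmr$retained),
              final = length(trace$final))
  cat(sprintf("[%s] retained after Spearman: %d; after mRMR: %d; final: %d\n",
              task, counts["spearman"], counts["mrmr"], counts["final"]))
  cat(sprintf("[%s] selected: %s\n", task, paste(trace$final, collapse = ", ")))
  write_selection_trace(trace, sprintf("results/selection_%s.json", task))
}
cat("Wrote selection_fpwt40.json, selection_tugt.json\n")
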