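# Stepwise feature selection: Spearman correlation filter, greedy
# minimum-redundancy maximum-relevance (mRMR), and sequential floating
# wrapper search, with a PCA dimensionality-reduction benchmark.
# Every statistic is computed from the training split only.

#' Spearman correlation filter
#'
#' Retains features whose absolute Spearman rank correlation with the
#' task label reaches the threshold (ties at the threshold are
#' retained). Constant features, whose correlation is undefined, are
#' dropped.
#'
#' @param X numeric feature matrix or data.frame (training split only).
#' @param y numeric label vector.
#' @param threshold minimum |rho| (default 0.2).
#' @return List (selection-trace stage): `stage`, `scores` (named rho for
#'   all non-constant features), `retained` (feature names).
#' @export
spearman_filter <- function(X, y, threshold = 0.2) {
  X <- as_feature_matrix(X)
  assert_that(nrow(X) >= 2, "need at least 2 training samples")
  sds <- apply(X, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  rho <- suppressWarnings(
    as.vector(stats::cor(X[, keep, drop = FALSE], y, method = "spearman"))
  )
  names(rho) <- colnames(X)[keep]
  retained <- names(rho)[!is.na(rho) & abs(rho) >= threshold]
  list(stage = "spearman", threshold = threshold, scores = rho, retained = retained)
}

#' Greedy mRMR feature ranking (MID variant)
#'
#' Forward greedy minimum-redundancy maximum-relevance for a continuous
#' target: relevance is the absolute Pearson correlation with the label,
#' redundancy the mean absolute correlation with already-selected
#' features, and the selection score their difference (the mutual
#' information difference form adapted to regression). The first feature
#' selected is the most relevant one.
#'
#' @param X numeric feature matrix or data.frame.
#' @param y numeric label vector.
#' @param k number of features to select (<= number of samples by the
#'   selection protocol; enforced against ncol(X) here).
#' @param redundancy_weight multiplier on the redundancy term (1 =
#'   standard MID; 0 reduces to top-k relevance ranking).
#' @return List stage: `stage`, `order` (feature names in selection
#'   order), `scores` (selection score at the step each feature was
#'   chosen), `retained`.
#' @export
mrmr_select <- function(X, y, k, redundancy_weight = 1) {
  X <- as_feature_matrix(X)
  assert_that(k > 0, "k must be positive")
  k <- min(k, ncol(X))
  rel <- abs(as.vector(suppressWarnings(stats::cor(X, y))))
  rel[is.na(rel)] <- 0
  names(rel) <- colnames(X)
  cx <- abs(suppressWarnings(stats::cor(X)))
  cx[is.na(cx)] <- 0

  selected <- integer(0)
  scores <- numeric(0)
  candidates <- seq_len(ncol(X))
  for (step in seq_len(k)) {
    red <- if (!length(selected)) {
      rep(0, length(candidates))
    } else {
      rowMeans(cx[candidates, selected, drop = FALSE])
    }
    sc <- rel[candidates] - redundancy_weight * red
    best <- which.max(sc)  # ties: first (column order) wins
    selected <- c(selected, candidates[best])
    scores <- c(scores, sc[best])
    candidates <- candidates[-best]
    if (!length(candidates)) break
  }
  nm <- colnames(X)[selected]
  list(stage = "mrmr", order = nm, scores = stats::setNames(scores, nm), retained = nm)
}

#' Random-forest predictor for wrapper scoring
#'
#' @param ntree number of trees.
#' @param seed integer seed for the forest.
#' @return A function `(X_train, y_train, X_new) -> predictions`.
#' @export
rf_predictor <- function(ntree = 100, seed = 1) {
  function(X_train, y_train, X_new) {
    fit <- with_seed(seed, randomForest::randomForest(X_train, y_train, ntree = ntree))
    as.numeric(stats::predict(fit, X_new))
  }
}

# Mean CV MAE of `predictor` on the feature subset `features`.
cv_mae <- function(X, y, features, folds, predictor) {
  maes <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    if (sum(!tr) < 1 || sum(tr) < 2) stopf("degenerate fold %d in wrapper CV", f)
    pred <- predictor(X[tr, features, drop = FALSE], y[tr], X[!tr, features, drop = FALSE])
    mean(abs(y[!tr] - pred))
  }, 0)
  mean(maes)
}

#' Sequential floating feature selection (SFFS / SBFS)
#'
#' Wrapper search scored by mean cross-validated MAE of a base model.
#' Forward selection starts from the empty set and adds the best
#' feature, then conditionally excludes features whose removal improves
#' the best score recorded at the smaller size (floating step).
#' Backward selection starts from the full set with the mirrored
#' conditional inclusion. Returns the best-scoring subset over all
#' visited sizes.
#'
#' @param X numeric feature matrix or data.frame.
#' @param y numeric label vector.
#' @param direction `"forward"` (SFFS) or `"backward"` (SBFS).
#' @param base_model predictor function as from [rf_predictor()].
#' @param cv number of CV folds (>= 2).
#' @param seed seed for the fold assignment.
#' @param max_size optional cap on the subset size explored (forward) /
#'   floor (backward reaches down to `min_size`).
#' @param min_size smallest subset size considered (default 1).
#' @return List stage: `stage`, `direction`, `subset` (best feature
#'   names), `score` (its CV MAE), `history` (data.frame: size, score,
#'   features).
#' @export
sequential_floating_select <- function(X, y,
                                       direction = c("forward", "backward"),
                                       base_model = rf_predictor(),
                                       cv = 5, seed = 1,
                                       max_size = NULL, min_size = 1) {
  direction <- match.arg(direction)
  X <- as_feature_matrix(X)
  assert_that(cv >= 2, "need at least 2 CV folds")
  p <- ncol(X)
  nm <- colnames(X)
  max_size <- min(max_size %||% p, p)
  folds <- make_folds(nrow(X), cv, seed)

  cache <- new.env(parent = emptyenv())
  score_of <- function(feats) {
    key <- paste(sort(feats), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- cv_mae(X, y, feats, folds, base_model)
    cache[[key]] <- s
    s
  }
  # best subset seen at each size (lower MAE is better)
  best_at <- vector("list", p)
  best_score_at <- rep(Inf, p)
  note <- function(feats) {
    s <- score_of(feats)
    k <- length(feats)
    if (s < best_score_at[k]) {
      best_score_at[k] <<- s
      best_at[[k]] <<- feats
    }
    s
  }

  if (direction == "forward") {
    cur <- character(0)
    while (length(cur) < max_size) {
      cands <- setdiff(nm, cur)
      sc <- vapply(cands, function(f) score_of(c(cur, f)), 0)
      cur <- c(cur, cands[which.min(sc)])
      note(cur)
      # conditional exclusion
      while (length(cur) > max(min_size, 1) + 1) {
        sc_rm <- vapply(cur, function(f) score_of(setdiff(cur, f)), 0)
        worst <- which.min(sc_rm)
        if (sc_rm[worst] < best_score_at[length(cur) - 1]) {
          cur <- setdiff(cur, cur[worst])
          note(cur)
        } else break
      }
    }
  } else {
    cur <- nm
    note(cur)
    while (length(cur) > min_size) {
      sc_rm <- vapply(cur, function(f) score_of(setdiff(cur, f)), 0)
      cur <- setdiff(cur, cur[which.min(sc_rm)])
      note(cur)
      # conditional inclusion
      while (length(cur) < p - 1) {
        cands <- setdiff(nm, cur)
        sc_add <- vapply(cands, function(f) score_of(c(cur, f)), 0)
        best <- which.min(sc_add)
        if (sc_add[best] < best_score_at[length(cur) + 1]) {
          cur <- c(cur, cands[best])
          note(cur)
        } else break
      }
    }
  }

  sizes <- which(is.finite(best_score_at))
  history <- data.frame(
    size = sizes,
    score = best_score_at[sizes],
    features = vapply(best_at[sizes], paste, "", collapse = ",")
  )
  k_best <- sizes[which.min(best_score_at[sizes])]
  list(stage = "wrapper",
       direction = if (direction == "forward") "sffs" else "sbfs",
       subset = best_at[[k_best]],
       score = best_score_at[k_best],
       history = history)
}

#' PCA dimensionality-reduction benchmark
#'
#' Cross-validated performance of the base model on the leading principal
#' components, the comparison benchmark for stepwise selection. Within
#' each fold, components are fitted on the standardized training fold
#' (count chosen by an explained-variance threshold) and the validation
#' fold is projected onto them.
#'
#' @param X numeric feature matrix or data.frame.
#' @param y numeric label vector.
#' @param base_model predictor function as from [rf_predictor()].
#' @param cv number of CV folds.
#' @param var_threshold cumulative explained-variance threshold used to
#'   pick the number of components (default 0.95).
#' @param seed seed for the fold assignment.
#' @return List: `metrics` (mae, mape, rmse across folds),
#'   `n_components` (chosen on the full data), `explained_variance`
#'   (per-component shares on the full data; sums to 1).
#' @export
pca_benchmark <- function(X, y, base_model = rf_predictor(), cv = 5,
                          var_threshold = 0.95, seed = 1) {
  X <- as_feature_matrix(X)
  folds <- make_folds(nrow(X), cv, seed)
  preds <- rep(NA_real_, nrow(X))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    std <- standardize_features(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    pc <- stats::prcomp(std$train, center = FALSE, scale. = FALSE)
    share <- pc$sdev^2 / sum(pc$sdev^2)
    ncomp <- max(1, which(cumsum(share) >= var_threshold)[1])
    rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
    preds[!tr] <- base_model(std$train %*% rot, y[tr], std$test %*% rot)
  }
  pc_full <- stats::prcomp(standardize_features(X), center = FALSE, scale. = FALSE)
  share_full <- pc_full$sdev^2 / sum(pc_full$sdev^2)
  list(
    metrics = evaluate_predictions(y, preds),
    n_components = max(1, which(cumsum(share_full) >= var_threshold)[1]),
    explained_variance = share_full
  )
}

#' Run the full selection cascade
#'
#' Spearman filter, then mRMR ranking capped at the training sample
#' count, then (optionally) the floating wrapper search. The returned
#' trace satisfies the containment invariant: final subset ⊆ mRMR subset
#' ⊆ Spearman-retained set.
#'
#' @param X training feature matrix or data.frame.
#' @param y training labels.
#' @param spearman_threshold minimum |rho| for the filter stage.
#' @param k mRMR subset size; defaults to the number of training samples.
#' @param wrapper `"sffs"`, `"sbfs"`, or `"none"`.
#' @param base_model wrapper base model (see [rf_predictor()]).
#' @param cv wrapper CV folds.
#' @param seed seed for wrapper fold assignment.
#' @param max_size optional wrapper subset-size cap.
#' @return A `selection_trace`: list with `stages` (per-stage results)
#'   and `final` (selected feature names).
#' @export
run_selection_cascade <- function(X, y, spearman_threshold = 0.2, k = NULL,
                                  wrapper = c("sbfs", "sffs", "none"),
                                  base_model = rf_predictor(), cv = 5, seed = 1,
                                  max_size = NULL) {
  wrapper <- match.arg(wrapper)
  X <- as_feature_matrix(X)
  k <- k %||% nrow(X)
  stages <- list()

  sp <- spearman_filter(X, y, spearman_threshold)
  stages$spearman <- sp
  if (!length(sp$retained)) stopf("no feature passes the Spearman filter")

  mr <- mrmr_select(X[, sp$retained, drop = FALSE], y, k = k)
  stages$mrmr <- mr
  final <- mr$retained

  if (wrapper != "none") {
    wr <- sequential_floating_select(
      X[, mr$retained, drop = FALSE], y,
      direction = if (wrapper == "sffs") "forward" else "backward",
      base_model = base_model, cv = cv, seed = seed, max_size = max_size
    )
    stages$wrapper <- wr
    final <- wr$subset
  }
  structure(list(stages = stages, final = final), class = "selection_trace")
}

#' Serialize a selection trace to JSON
#'
#' @param trace a `selection_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  jsonlite::write_json(trace, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
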