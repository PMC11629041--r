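test_that("Spearman filter keeps monotone associations and drops constants", {
  set.seed(1)
  y <- runif(40, 10, 30)
  X <- cbind(mono = y^3, const = rep(2, 40), noise = rnorm(40))
  st <- spearman_filter(X, y)
  expect_equal(st$scores[["mono"]], 1)
  expect_true("mono" %in% st$retained)
  expect_false("const" %in% names(st$scores))
  expect_error(spearman_filter(X[1, , drop = FALSE], y[1]), "2 training samples")
})

test_that("planted-signal features survive the Spearman filter more often than noise", {
  hits_signal <- hits_noise <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    ch <- planted_feature_cohort(n = 60, p = 20, seed = r)
    ret <- spearman_filter(ch$X, ch$y)$retained
    hits_signal <- hits_signal + mean(ch$informative %in% ret)
    hits_noise <- hits_noise + mean(setdiff(colnames(ch$X), ch$informative) %in% ret)
  }
  expect_gt(hits_signal / reps, hits_noise / reps)
  expect_gt(hits_signal / reps, 0.9)
})

test_that("mRMR greedy selection matches a brute-force reimplementation", {
  set.seed(2)
  X <- matrix(rnorm(30 * 8), 30, 8)
  colnames(X) <- paste0("v", 1:8)
  X[, 2] <- X[, 1]  # exact duplicate
  y <- X[, 1] + 0.5 * X[, 3] + rnorm(30, 0, 0.2)
  res <- mrmr_select(X, y, k = 3)

  # independent greedy oracle
  rel <- abs(cor(X, y))[, 1]
  sel <- names(which.max(rel))
  for (step in 2:3) {
    cand <- setdiff(colnames(X), sel)
    sc <- sapply(cand, function(f) {
      rel[f] - mean(abs(cor(X[, f], X[, sel, drop = FALSE])))
    })
    sel <- c(sel, cand[which.max(sc)])
  }
  expect_identical(res$order, sel)
  expect_identical(res$order[1], names(which.max(rel)))
  expect_false(res$order[2] %in% c("v2", "v1")[match(res$order[1], c("v1", "v2"))])
  expect_error(mrmr_select(X, y, k = 0), "positive")
})

test_that("mRMR without redundancy weighting reduces to top-k relevance", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6); colnames(X) <- paste0("v", 1:6)
  y <- rnorm(40)
  res <- mrmr_select(X, y, k = 6, redundancy_weight = 0)
  rel <- abs(cor(X, y))[, 1]
  expect_identical(res$order, names(sort(rel, decreasing = TRUE)))
})

test_that("floating selection recovers planted features on a small instance", {
  ch <- planted_feature_cohort(n = 60, p = 8, n_informative = 2,
                               beta = c(4, 3), noise_sd = 0.5, seed = 5)
  for (dir in c("forward", "backward")) {
    res <- sequential_floating_select(ch$X, ch$y, direction = dir,
                                      base_model = rf_predictor(60, seed = 1),
                                      cv = 5, seed = 1)
    expect_true(all(ch$informative %in% res$subset))
    expect_identical(res$stage, "wrapper")
  }
  # SBFS visits the full set; SFFS builds up from a single feature
  resb <- sequential_floating_select(ch$X, ch$y, "backward",
                                     base_model = rf_predictor(30, 1), seed = 1)
  expect_true(ncol(ch$X) %in% resb$history$size)
  resf <- sequential_floating_select(ch$X, ch$y, "forward",
                                     base_model = rf_predictor(30, 1), seed = 1,
                                     max_size = 3)
  expect_equal(min(resf$history$size), 1)
})

test_that("cascade output respects stage containment", {
  ch <- planted_feature_cohort(n = 50, p = 15, seed = 7)
  tr <- run_selection_cascade(ch$X, ch$y, k = 8, wrapper = "sffs",
                              base_model = rf_predictor(50, 1), seed = 1,
                              max_size = 5)
  expect_true(all(tr$final %in% tr$stages$mrmr$retained))
  expect_true(all(tr$stages$mrmr$retained %in% tr$stages$spearman$retained))
  expect_lte(length(tr$stages$mrmr$retained), 8)
})

test_that("selection statistics depend on the training split alone", {
  ch <- planted_feature_cohort(n = 60, p = 12, seed = 9)
  split <- holdout_split(60, seed = 4)
  run <- function(X) run_selection_cascade(X[split$train, ], ch$y[split$train],
                                           k = 6, wrapper = "sffs",
                                           base_model = rf_predictor(40, 1),
                                           seed = 2, max_size = 4)
  t1 <- run(ch$X)
  Xp <- ch$X
  Xp[split$test, ] <- Xp[split$test, ] + 100  # perturb the held-out rows
  t2 <- run(Xp)
  expect_identical(t1, t2)
})

test_that("PCA benchmark reports coherent components and variance shares", {
  set.seed(10)
  X <- cbind(a = rnorm(40, sd = 5), b = rnorm(40, sd = 0.1), c = rnorm(40, sd = 0.1))
  y <- abs(X[, 1]) + 15
  pb <- pca_benchmark(X, y, base_model = rf_predictor(40, 1), var_threshold = 0.6,
                      seed = 1)
  expect_equal(sum(pb$explained_variance), 1)
  expect_true(all(pb$metrics >= 0))
  expect_gte(pb$n_components, 1)
})
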