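# Shared fixtures, built in code. Recordings are cached per parameter set
# so test files reuse them without regeneration.

.fixture_cache <- new.env(parent = emptyenv())

fixture_recording <- function(jitter = 0, asym = 0, seed = 1, n_cycles = 55,
                              cycle_duration = 1.1, body_weight = 60) {
  key <- paste(jitter, asym, seed, n_cycles, cycle_duration, body_weight, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    p <- waveform_params(cycle_duration = cycle_duration, n_cycles = n_cycles,
                         cycle_jitter_sd = jitter, asym_amp = asym, seed = seed)
    .fixture_cache[[key]] <- generate_recording(p, body_weight = body_weight)
  }
  .fixture_cache[[key]]
}

fixture_physical <- function() list(age = 62, height = 158, weight = 60, bmi = 24)

fixture_features <- function(...) {
  key <- paste0("feat_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- extract_participant_features(
      fixture_recording(...), fixture_physical())
  }
  .fixture_cache[[key]]
}

# A random but landmark-consistent gait cycle for brute-force oracles:
# nonnegative 8-channel matrix with fixed relative landmarks.
random_cycle <- function(seed, n = 24) {
  set.seed(seed)
  mat <- matrix(abs(rnorm(n * 8, 0.1, 0.08)), n, 8)
  structure(list(
    mat = mat,
    landmarks = list(heel_strike = 1L, peak1 = 6L, valley = 10L, peak2 = 14L,
                     toe_off = 19L, cycle_end = as.integer(n)),
    dt = 0.05
  ), class = "gait_cycle")
}

# Feature-level planted-signal cohort for selection/model tests:
# first `n_informative` columns carry the signal, the rest are noise.
planted_feature_cohort <- function(n, p = 20, n_informative = 3,
                                   beta = c(3, 2, 1.5), noise_sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  y <- 20 + as.numeric(X[, seq_len(n_informative), drop = FALSE] %*%
                         beta[seq_len(n_informative)]) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, informative = colnames(X)[seq_len(n_informative)])
}

# Printed training-set cross-validation metric triples and relative-index
# column (40-m fast-paced walk test and timed up-and-go test tasks).
published_ri_tables <- function() {
  t5 <- read.csv(text = "model,mae,mape,rmse,ri
baseline,4.925,16.461,6.219,0
lr,3.793,12.426,4.966,0.676
svm,3.318,10.653,4.526,0.951
rf,2.59,8.407,3.546,1.393
adaboost,2.541,8.137,3.546,1.42
xgboost,2.495,7.758,3.527,1.455
lgbm,2.373,7.473,3.381,1.521
stack_linear,2.518,7.921,3.432,1.456
stack_svm,2.223,6.929,3.152,1.621
sae,2.345,7.42,3.334,1.537
wae,2.34,7.399,3.329,1.54")
  t6 <- read.csv(text = "model,mae,mape,rmse,ri
baseline,2.475,20.969,3.267,0
lr,1.739,14.174,2.285,0.922
svm,1.717,13.859,2.318,0.936
rf,1.538,12.396,2.16,1.126
adaboost,1.399,11.218,2.043,1.274
xgboost,1.306,10.365,1.891,1.399
lgbm,1.397,11.012,1.944,1.315
stack_linear,1.473,11.775,2.033,1.221
stack_svm,1.3,10.2,1.873,1.415
sae,1.347,10.701,1.945,1.35
wae,1.339,10.633,1.936,1.359")
  list(fpwt40 = t5, tugt = t6)
}

metric_vec <- function(row) c(mae = row$mae, mape = row$mape, rmse = row$rmse)
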