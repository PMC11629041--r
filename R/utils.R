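#' @keywords internal
"_PACKAGE"

# Sampling interval is fixed by the insole hardware: 20 Hz.
SAMPLING_RATE <- 20
DT <- 1 / SAMPLING_RATE

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Seeded evaluation that restores the caller's RNG state
#'
#' All stochastic stages take an explicit integer seed; evaluating under
#' `with_seed()` keeps package functions from clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' K-fold assignment for cross-validation
#'
#' Plain shuffled (unstratified) folds, as appropriate for a continuous
#' regression target.
#'
#' @param n number of samples.
#' @param k number of folds (>= 2).
#' @param seed integer seed controlling the shuffle.
#' @return Integer vector of length `n` with fold labels in `1..k`.
#' @export
make_folds <- function(n, k = 5, seed = 1) {
  assert_that(n >= k, "cannot make %d folds from %d samples", k, n)
  assert_that(k >= 2, "need at least 2 folds, got %d", k)
  idx <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[idx] <- rep_len(seq_len(k), n)
  folds
}

# Trapezoidal integral of a regularly sampled series.
trapz_dt <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

# Column-impute NAs with training-split means (missing-value policy:
# undefined ratios propagate as NA and are mean-imputed within the
# training split before modelling).
impute_train_means <- function(X_train, X_test = NULL) {
  mu <- colMeans(X_train, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  fill <- function(X) {
    for (j in seq_len(ncol(X))) {
      bad <- !is.finite(X[, j])
      if (any(bad)) X[bad, j] <- mu[j]
    }
    X
  }
  if (is.null(X_test)) fill(X_train) else list(train = fill(X_train), test = fill(X_test))
}

#' Z-score standardization using training-split statistics
#'
#' @param X_train,X_test numeric matrices (test optional).
#' @return Standardized matrix, or list with `train` and `test` when a test
#'   matrix is supplied. Zero-variance columns are centred but not scaled.
#' @export
standardize_features <- function(X_train, X_test = NULL) {
  mu <- colMeans(X_train)
  sd <- apply(X_train, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  tr <- sweep(sweep(X_train, 2, mu), 2, sd, "/")
  if (is.null(X_test)) return(tr)
  te <- sweep(sweep(X_test, 2, mu), 2, sd, "/")
  list(train = tr, test = te)
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}
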