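#' Cube-root transform for tumour volumes
#'
#' A volume is the product of three linear dimensions, so its cube root is on
#' the scale of a single dimension; regression targets are cube-rooted before
#' model fitting. The transform is strictly increasing, so the ordering of
#' responses is preserved.
#'
#' @param volumes Numeric vector of strictly positive volumes.
#' @return `volumes^(1/3)`.
#' @export
cube_root <- function(volumes) {
  if (!is.numeric(volumes) || length(volumes) == 0L) {
    stop("volumes must be a nonempty numeric vector")
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("cube_root requires strictly positive finite volumes; ",
         "filter invalid rows with compute_volumes() first")
  }
  volumes^(1 / 3)
}

#' Learn feature-wise standardization statistics on a training set
#'
#' Means and standard deviations (sample, N-1 denominator) are computed per
#' column of the training matrix only; test data are later transformed with
#' these same statistics so that no test information leaks into the model.
#' Zero-variance training columns carry no information and are mapped to
#' exactly 0 for any input.
#'
#' @param x_train Numeric training matrix (samples x features).
#' @return An object of class `standardizer` with fields `center`, `scale`
#'   and `zero_var` (logical per column).
#' @seealso [apply_standardizer()]
#' @export
fit_standardizer <- function(x_train) {
  x_train <- as.matrix(x_train)
  if (nrow(x_train) < 1L) stop("x_train must be nonempty")
  center <- colMeans(x_train)
  scale <- apply(x_train, 2L, stats::sd)
  if (nrow(x_train) == 1L) scale <- rep(0, ncol(x_train))
  if (any(!is.finite(center)) || any(!is.finite(scale))) {
    stop("non-finite values in training matrix")
  }
  zero_var <- scale <= 0
  scale[zero_var] <- 1
  structure(list(center = center, scale = scale, zero_var = zero_var),
            class = "standardizer")
}

#' Apply a fitted standardizer to a matrix
#'
#' @param s A `standardizer` from [fit_standardizer()].
#' @param x Numeric matrix with the same columns as the training matrix.
#' @return The standardized matrix; training-set columns come out with mean 0
#'   and unit (sample) standard deviation, zero-variance columns as all 0.
#' @export
apply_standardizer <- function(s, x) {
  stopifnot(inherits(s, "standardizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(s$center)) {
    stop("column count mismatch: standardizer was fitted on ",
         length(s$center), " features, input has ", ncol(x))
  }
  out <- sweep(sweep(x, 2L, s$center, "-"), 2L, s$scale, "/")
  if (any(s$zero_var)) out[, s$zero_var] <- 0
  out
}

#' @export
print.standardizer <- function(x, ...) {
  cat("Standardizer over", length(x$center), "features (",
      sum(x$zero_var), "constant )\n")
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library randomness never perturbs user code.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Draw a reproducible train/test split
#'
#' Uniformly random partition of `1:n` into a training part holding
#' `round(train_frac * n)` samples and a test part holding the rest, as used
#' by each replication of the evaluation protocol (80/20 by default).
#'
#' @param n Number of samples (at least 5).
#' @param seed Integer seed; the same seed always yields the same split.
#' @param train_frac Training fraction, default 0.8.
#' @return A list of class `split_plan` with sorted integer vectors `train`
#'   and `test` and the `seed`.
#' @export
make_split <- function(n, seed, train_frac = 0.8) {
  if (n < 5L) stop("need at least 5 samples to form a train/test split")
  stopifnot(train_frac > 0, train_frac < 1)
  n_train <- round(train_frac * n)
  train <- with_local_seed(seed, sort(sample.int(n, n_train)))
  structure(list(train = train, test = sort(setdiff(seq_len(n), train)),
                 seed = seed),
            class = "split_plan")
}

#' Assign samples to cross-validation folds
#'
#' @param n Number of samples.
#' @param k Number of folds (default 4).
#' @param seed Integer seed.
#' @return Integer vector of length `n` with fold labels in `1:k`; fold sizes
#'   differ by at most one.
#' @export
make_folds <- function(n, k = 4L, seed = 1L) {
  if (k < 2L) stop("need at least 2 folds")
  if (n < k) stop("fewer samples than folds")
  with_local_seed(seed, sample(rep_len(seq_len(k), n)))
}
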