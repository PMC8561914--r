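#' Gaussian kernel width by the mean pairwise distance heuristic
#'
#' The kernel width sigma of each per-pathway Gaussian kernel is set to the
#' mean Euclidean distance over all unordered pairs of training samples,
#' computed on the pathway's own sub-matrix. The heuristic is scale-
#' equivariant: scaling the sub-matrix by c scales sigma by c and leaves the
#' resulting kernel matrix unchanged.
#'
#' @param x_sub Numeric matrix (training samples x matched genes).
#' @param zero_fallback What to do when all samples coincide (sigma would be
#'   0): `"error"` (default) or `"one"` to fall back to sigma = 1 with a
#'   warning (the kernel is then all ones, harmless inside a convex
#'   combination).
#' @return Positive scalar sigma.
#' @export
estimate_width <- function(x_sub, zero_fallback = c("error", "one")) {
  zero_fallback <- match.arg(zero_fallback)
  x_sub <- as.matrix(x_sub)
  if (nrow(x_sub) < 2L) stop("need at least 2 training samples")
  sigma <- mean(stats::dist(x_sub))
  if (!is.finite(sigma)) stop("non-finite pairwise distances")
  if (sigma <= 0) {
    if (zero_fallback == "error") {
      stop("all training samples identical on this sub-matrix (sigma = 0); ",
           "use zero_fallback = \"one\" to substitute sigma = 1")
    }
    warning("sigma = 0 on a degenerate sub-matrix; falling back to sigma = 1")
    sigma <- 1
  }
  sigma
}

#' Gaussian kernel matrix
#'
#' Entry (i, j) is `exp(-||a_i - b_j||^2 / (2 sigma^2))`; values lie in
#' (0, 1] and the diagonal of a square self-kernel is exactly 1.
#'
#' @param x_a Numeric matrix (rows are samples).
#' @param x_b Numeric matrix with the same number of columns; defaults to
#'   `x_a`, giving the symmetric training kernel.
#' @param sigma Positive kernel width.
#' @return `nrow(x_a)` x `nrow(x_b)` kernel matrix.
#' @export
gaussian_kernel <- function(x_a, x_b = x_a, sigma) {
  symmetric <- missing(x_b)
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar")
  }
  if (ncol(x_a) != ncol(x_b)) {
    stop("dimension mismatch: ", ncol(x_a), " vs ", ncol(x_b), " columns")
  }
  d2 <- outer(rowSums(x_a^2), rowSums(x_b^2), "+") - 2 * tcrossprod(x_a, x_b)
  d2[d2 < 0] <- 0  # round-off from the expansion
  k <- exp(-d2 / (2 * sigma^2))
  if (symmetric) {
    k <- (k + t(k)) / 2
    diag(k) <- 1
  }
  k
}

#' Build one Gaussian kernel per gene set
#'
#' For every gene set with at least one matched expression column, computes
#' the set's own kernel width on the (standardized) training sub-matrix and
#' the corresponding training kernel matrix. Sets that matched no column are
#' dropped with a warning.
#'
#' @param x_train_std Standardized training expression matrix
#'   (samples x genes).
#' @param partition A `feature_partition` from [map_to_features()].
#' @return An object of class `kernel_stack` with fields `kernels` (list of
#'   N x N matrices), `sigmas`, `set_names`, `indices` (matched column indices
#'   per retained set) and `x_train` (kept for cross-kernel computation at
#'   prediction time).
#' @export
build_kernel_stack <- function(x_train_std, partition) {
  stopifnot(inherits(partition, "feature_partition"))
  x_train_std <- as.matrix(x_train_std)
  keep <- names(partition$indices)[partition$n_matched > 0L]
  if (length(partition$empty) > 0L) {
    warning("dropping ", length(partition$empty),
            " gene set(s) with no matched genes")
  }
  if (length(keep) == 0L) {
    stop("no gene set matched any expression column; cannot build kernels")
  }
  idx <- partition$indices[keep]
  bad <- unlist(idx)[unlist(idx) > ncol(x_train_std)]
  if (length(bad) > 0L) stop("partition indices exceed matrix columns")
  sigmas <- numeric(length(keep))
  kernels <- vector("list", length(keep))
  for (m in seq_along(keep)) {
    sub <- x_train_std[, idx[[m]], drop = FALSE]
    sigmas[m] <- estimate_width(sub, zero_fallback = "one")
    kernels[[m]] <- gaussian_kernel(sub, sigma = sigmas[m])
  }
  names(kernels) <- keep
  names(sigmas) <- keep
  structure(list(kernels = kernels, sigmas = sigmas, set_names = keep,
                 indices = idx, x_train = x_train_std),
            class = "kernel_stack")
}

#' @export
print.kernel_stack <- function(x, ...) {
  cat("Kernel stack:", length(x$kernels), "Gaussian kernels on",
      nrow(x$x_train), "training samples\n")
  invisible(x)
}

#' Cross-kernels between new samples and the training set
#'
#' Reuses each kernel's training-time width and column indices; rows index
#' the new samples, columns the training samples.
#'
#' @param stack A `kernel_stack`.
#' @param x_new_std New samples, standardized with the training statistics.
#' @return List of M x N cross-kernel matrices, one per retained set.
#' @export
cross_kernel_stack <- function(stack, x_new_std) {
  stopifnot(inherits(stack, "kernel_stack"))
  x_new_std <- as.matrix(x_new_std)
  if (ncol(x_new_std) != ncol(stack$x_train)) {
    stop("new data must have the training matrix's columns")
  }
  out <- lapply(seq_along(stack$sigmas), function(m) {
    idx <- stack$indices[[m]]
    gaussian_kernel(x_new_std[, idx, drop = FALSE],
                    stack$x_train[, idx, drop = FALSE],
                    sigma = stack$sigmas[[m]])
  })
  names(out) <- stack$set_names
  out
}

#' Convex combination of a kernel stack
#'
#' @param kernels A `kernel_stack` or a plain list of conformable kernel
#'   matrices.
#' @param eta Simplex weights: non-negative, summing to 1 (within 1e-8), one
#'   per kernel.
#' @return The weighted sum `sum_m eta_m K_m`.
#' @export
combine_kernels <- function(kernels, eta) {
  klist <- if (inherits(kernels, "kernel_stack")) kernels$kernels else kernels
  if (length(eta) != length(klist)) {
    stop("eta has length ", length(eta), " but there are ",
         length(klist), " kernels")
  }
  if (any(eta < -1e-12)) stop("negative kernel weight")
  if (abs(sum(eta) - 1) > 1e-8) {
    stop("kernel weights must sum to 1 (got ", format(sum(eta)), ")")
  }
  out <- matrix(0, nrow(klist[[1]]), ncol(klist[[1]]))
  for (m in seq_along(klist)) {
    if (eta[m] != 0) out <- out + eta[m] * klist[[m]]
  }
  out
}
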