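# Independent oracles used by the test suite. These deliberately share no
# code with the package's solvers: the SVR dual oracle is an accelerated
# projected-gradient method run to high precision, and the signed-rank
# oracle enumerates all sign assignments.

# Euclidean projection onto {0 <= x <= C, sum over alpha+ minus alpha- = 0}
# by bisection on the equality multiplier.
oracle_project <- function(v, C, n) {
  s <- c(rep(1, n), rep(-1, n))
  f <- function(lam) sum(s * pmin(pmax(v - lam * s, 0), C))
  lo <- -max(abs(v)) - C - 1
  hi <- -lo
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  pmin(pmax(v - (lo + hi) / 2 * s, 0), C)
}

oracle_dual_objective <- function(a, K, y, eps) {
  n <- length(y)
  b <- a[1:n] - a[(n + 1):(2 * n)]
  -sum(y * b) + eps * sum(a) + 0.5 * drop(crossprod(b, K %*% b))
}

# FISTA with restarts on the 2N dual; stops when a full restart block no
# longer improves the objective beyond 1e-13.
oracle_svr_dual <- function(K, y, C, eps, blocks = 30L, block_size = 2000L) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K))
  g0 <- c(-y + eps, y + eps)
  L <- 2 * max(eigen(K, symmetric = TRUE, only.values = TRUE)$values) + 1e-12
  x <- rep(0, 2 * n); z <- x; t0 <- 1
  best <- x; best_obj <- oracle_dual_objective(x, K, y, eps)
  for (bl in seq_len(blocks)) {
    for (k in seq_len(block_size)) {
      grad <- drop(H %*% z) + g0
      xn <- oracle_project(z - grad / L, C, n)
      t1 <- (1 + sqrt(1 + 4 * t0^2)) / 2
      z <- xn + ((t0 - 1) / t1) * (xn - x)
      x <- xn; t0 <- t1
    }
    o <- oracle_dual_objective(x, K, y, eps)
    improved <- o < best_obj - 1e-13
    if (o < best_obj) {
      best <- x
      best_obj <- o
    }
    if (!improved) break
    z <- x; t0 <- 1  # restart acceleration from the best point
  }
  n_ <- length(y)
  list(alpha_plus = best[1:n_], alpha_minus = best[(n_ + 1):(2 * n_)],
       beta = best[1:n_] - best[(n_ + 1):(2 * n_)], objective = best_obj)
}

# Random small Gaussian-kernel SVR instance with the mean-distance width.
random_svr_instance <- function(n = NULL, C = NULL, eps = NULL) {
  if (is.null(n)) n <- sample(8:20, 1)
  d <- sample(2:6, 1)
  X <- matrix(stats::rnorm(n * d), n)
  sigma <- mean(stats::dist(X))
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * sigma^2))
  y <- sin(X[, 1]) + 0.5 * X[, 2]^2 + stats::rnorm(n, 0, 0.1)
  list(K = K, y = y, X = X, sigma = sigma,
       C = if (is.null(C)) sample(c(0.5, 1, 10), 1) else C,
       eps = if (is.null(eps)) stats::runif(1, 0.05, 0.3) else eps)
}

# Exact two-sided signed-rank p-value by enumerating all 2^m sign
# assignments of the nonzero paired differences (ties in ranks are fine:
# the enumeration conditions on the observed absolute values).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  stopifnot(m >= 1, m <= 12)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- drop(signs %*% rk)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small standardized cohort + kernel stack for MKL tests.
make_test_stack <- function(n = 40, n_genes = 60, n_sets = 4, seed = 7,
                            informative = 1L) {
  spec <- synthetic_spec(n_samples = n, n_genes = n_genes, n_sets = n_sets,
                         informative_sets = informative, seed = seed)
  cohort <- generate_cohort(spec)
  std <- fit_standardizer(cohort$expression)
  x_std <- apply_standardizer(std, cohort$expression)
  partition <- map_to_features(cohort$sets, colnames(cohort$expression))
  list(stack = build_kernel_stack(x_std, partition),
       y = cube_root(cohort$volumes), x_std = x_std,
       cohort = cohort, partition = partition, std = std)
}
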