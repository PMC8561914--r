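# Closed-form toy problem: y = x on x = 0..3 with a linear kernel, C = 10,
# eps = 0.1. By symmetry beta = (-a, 0, 0, a) and the dual objective reduces
# to -2.8 a + 4.5 a^2, minimized at a = 14/45 with value -0.43555..., and
# both free support vectors pin the intercept at b = 0.1.
toy_linear <- function() {
  x <- c(0, 1, 2, 3)
  list(K = outer(x, x), y = c(0, 1, 2, 3), C = 10, eps = 0.1,
       a = 14 / 45, obj = -2.8 * (14 / 45) + 4.5 * (14 / 45)^2, b = 0.1)
}

test_that("toy problem matches the hand-derived solution", {
  t <- toy_linear()
  sol <- solve_svr_dual(t$K, t$y, t$C, t$eps)
  expect_equal(sol$alpha, c(-t$a, 0, 0, t$a), tolerance = 1e-6)
  expect_equal(sol$objective, t$obj, tolerance = 1e-8)
  expect_equal(sol$b, t$b, tolerance = 1e-6)
  # in-tube residuals for strictly-inside-the-box coefficients
  fitted <- predict(sol, t$K)
  inside <- abs(sol$alpha) < t$C - 1e-8
  expect_true(all(abs(t$y - fitted)[inside] <= t$eps + 1e-6))
})

test_that("a tube covering the data yields the all-zero constant model", {
  set.seed(2)
  y <- rnorm(8)
  K <- gaussian_kernel(matrix(rnorm(16), 8), sigma = 1.5)
  eps <- diff(range(y)) + 0.5
  sol <- solve_svr_dual(K, y, C = 5, epsilon = eps)
  expect_lt(max(abs(sol$alpha)), 1e-6)
  # b is the midpoint of the KKT interval [max(y) - eps, min(y) + eps]
  expect_equal(sol$b, (max(y) - eps + min(y) + eps) / 2, tolerance = 1e-6)
  expect_equal(predict(sol, K), rep(sol$b, 8), tolerance = 1e-6)
  expect_lt(abs(sol$objective), 2e-6)
})

test_that("solutions satisfy box, equality and complementarity constraints", {
  set.seed(11)
  for (i in 1:8) {
    p <- random_svr_instance()
    sol <- solve_svr_dual(p$K, p$y, p$C, p$eps)
    expect_true(all(sol$alpha_plus >= -1e-8 & sol$alpha_plus <= p$C + 1e-8))
    expect_true(all(sol$alpha_minus >= -1e-8 & sol$alpha_minus <= p$C + 1e-8))
    expect_lt(abs(sum(sol$alpha)), 1e-8)
    expect_lt(max(pmin(sol$alpha_plus, sol$alpha_minus)), 1e-8)
    expect_lte(sol$gap, 1e-6 * max(1, abs(sol$objective)) + 1e-6)
  }
})

test_that("solver optimum beats random feasible points", {
  set.seed(21)
  p <- random_svr_instance(n = 12)
  sol <- solve_svr_dual(p$K, p$y, p$C, p$eps)
  n <- length(p$y)
  for (i in 1:100) {
    v <- runif(2 * n, 0, p$C)
    a <- oracle_project(v, p$C, n)
    expect_gte(oracle_dual_objective(a, p$K, p$y, p$eps) + 1e-10,
               sol$objective)
  }
})

test_that("duplicate samples with equal response keep permutation symmetry", {
  x <- c(0.3, 0.3, 1.1, 2.0)
  K <- gaussian_kernel(matrix(x), sigma = 1)
  y <- c(0.5, 0.5, 1.4, 2.2)
  sol <- solve_svr_dual(K, y, C = 2, epsilon = 0.05)
  perm <- c(2, 1, 3, 4)
  sol_p <- solve_svr_dual(K[perm, perm], y[perm], C = 2, epsilon = 0.05)
  expect_equal(sol_p$objective, sol$objective, tolerance = 1e-8)
  expect_equal(predict(sol_p, K[perm, perm])[perm],
               predict(sol, K), tolerance = 1e-6)
})

test_that("training error is monotone non-increasing in C", {
  set.seed(31)
  p <- random_svr_instance(n = 15, eps = 0.1)
  eps_loss <- function(C) {
    sol <- solve_svr_dual(p$K, p$y, C, p$eps)
    mean(pmax(abs(p$y - predict(sol, p$K)) - p$eps, 0))
  }
  losses <- vapply(c(0.01, 0.1, 1, 10, 100), eps_loss, numeric(1))
  expect_true(all(diff(losses) <= 1e-6))
})

test_that("dual objective evaluation matches its definition", {
  set.seed(41)
  p <- random_svr_instance(n = 10)
  n <- 10
  a <- oracle_project(runif(2 * n, 0, p$C), p$C, n)
  expect_equal(svr_dual_objective(a[1:n], a[(n + 1):(2 * n)], p$K, p$y, p$eps),
               oracle_dual_objective(a, p$K, p$y, p$eps))
  expect_equal(svr_dual_objective(rep(0, n), rep(0, n), p$K, p$y, p$eps), 0)
})

test_that("fitted values agree with a reference epsilon-SVR implementation", {
  skip_if_not_installed("e1071")
  set.seed(51)
  for (i in 1:5) {
    n <- sample(15:30, 1)
    X <- matrix(rnorm(n * 3), n)
    y <- X[, 1]^2 + rnorm(n, 0, 0.2)
    sigma <- mean(dist(X))
    C <- 10; eps <- 0.1
    K <- gaussian_kernel(X, sigma = sigma)
    ours <- predict(solve_svr_dual(K, y, C, eps), K)
    ref <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                      gamma = 1 / (2 * sigma^2), cost = C, epsilon = eps,
                      scale = FALSE, tolerance = 1e-6)
    expect_equal(ours, unname(predict(ref, X)), tolerance = 1e-4)
  }
})

test_that("solver rejects invalid inputs", {
  K <- diag(3)
  expect_error(solve_svr_dual(K, c(1, NA, 2), 1, 0.1), "NaN|finite")
  expect_error(solve_svr_dual(K, 1:2, 1, 0.1), "N x N")
  expect_error(solve_svr_dual(K, 1:3, -1, 0.1), "positive")
  expect_error(solve_svr_dual(K, 1:3, 1, -0.1), "non-negative")
  expect_error(predict(solve_svr_dual(K, c(1, 2, 3), 1, 10), matrix(1, 2, 2)),
               "columns")
})
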