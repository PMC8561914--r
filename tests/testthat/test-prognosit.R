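test_that("init_eta spreads unit mass uniformly", {
  expect_equal(init_eta(1), 1)
  expect_equal(init_eta(4), rep(0.25, 4))
  for (p in c(2, 7, 50)) expect_equal(sum(init_eta(p)), 1)
  expect_error(init_eta(0), ">= 1")
})

test_that("update_eta applies the multiplicative rule", {
  # two kernels with quadratic forms 4 and 1: eta' = (2/3, 1/3)
  k1 <- diag(2) * 2; k2 <- diag(2) * 0.5
  alpha <- c(1, 1)
  expect_equal(update_eta(c(0.5, 0.5), alpha, list(k1, k2)), c(2 / 3, 1 / 3))
  # identical kernels keep symmetric weights
  expect_equal(update_eta(c(0.5, 0.5), alpha, list(k1, k1)), c(0.5, 0.5))
  # single kernel is always weight 1
  expect_equal(update_eta(1, alpha, list(k1)), 1)
})

test_that("update_eta is scale-invariant in alpha and keeps the simplex", {
  h <- make_test_stack(n = 15, n_genes = 40, n_sets = 4)
  set.seed(6)
  eta <- init_eta(4)
  alpha <- rnorm(15); alpha <- alpha - mean(alpha)
  e1 <- update_eta(eta, alpha, h$stack)
  expect_equal(sum(e1), 1, tolerance = 1e-12)
  expect_true(all(e1 >= 0))
  expect_equal(update_eta(eta, 17.3 * alpha, h$stack), e1)
})

test_that("exact zeros of eta are absorbing under the update", {
  h <- make_test_stack(n = 15, n_genes = 40, n_sets = 4)
  set.seed(7)
  alpha <- rnorm(15); alpha <- alpha - mean(alpha)
  eta <- c(0, 0.4, 0.6, 0)
  for (i in 1:5) {
    eta <- update_eta(eta, alpha, h$stack)
    expect_identical(eta[c(1, 4)], c(0, 0))
    expect_equal(sum(eta), 1, tolerance = 1e-12)
  }
})

test_that("all-zero alpha is signalled as a degenerate state", {
  h <- make_test_stack(n = 15, n_genes = 40, n_sets = 4)
  eta <- init_eta(4)
  out <- update_eta(eta, rep(0, 15), h$stack)
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_equal(as.numeric(out), eta)
  # the fit loop returns the constant model with a warning
  expect_warning(
    m <- prognosit_fit(h$stack, h$y, C = 1,
                       epsilon = diff(range(h$y)) + 1),
    "zero")
  expect_true(m$degenerate)
  expect_equal(as.numeric(m$eta), init_eta(4))
  expect_equal(predict(m, h$x_std), rep(m$solution$b, nrow(h$x_std)),
               tolerance = 1e-6)
})

test_that("with a single kernel the MKL model reduces to plain SVR", {
  h <- make_test_stack(n = 30, n_genes = 30, n_sets = 1)
  m <- prognosit_fit(h$stack, h$y, C = 1, epsilon = 0.1 * sd(h$y))
  expect_equal(as.numeric(m$eta), 1)
  expect_true(all(m$eta_trace == 1))
  sol <- solve_svr_dual(h$stack$kernels[[1]], h$y, 1, 0.1 * sd(h$y))
  expect_equal(predict(m, h$x_std),
               predict(sol, h$stack$kernels[[1]]), tolerance = 1e-8)
})

test_that("eta stays on the simplex and the nested objective decreases", {
  h <- make_test_stack(n = 40, n_genes = 60, n_sets = 4)
  m <- prognosit_fit(h$stack, h$y, C = 1, epsilon = 0.25 * sd(h$y))
  expect_lt(max(abs(rowSums(m$eta_trace) - 1)), 1e-10)
  expect_true(all(m$eta_trace >= 0))
  # the nested MKL objective is the negative of the recorded dual value
  expect_true(all(diff(-m$trace$objective) <= 1e-6))
})

test_that("duplicating a kernel splits its weight mass", {
  h <- make_test_stack(n = 30, n_genes = 60, n_sets = 3)
  eps <- 0.25 * sd(h$y)
  m1 <- prognosit_fit(h$stack, h$y, C = 1, epsilon = eps)
  part2 <- h$partition
  part2$indices <- c(part2$indices, list(DUP1 = part2$indices[[1]]))
  part2$n_matched <- c(part2$n_matched, DUP1 = part2$n_matched[[1]])
  stack2 <- build_kernel_stack(h$x_std, part2)
  m2 <- prognosit_fit(stack2, h$y, C = 1, epsilon = eps)
  expect_equal(m2$eta[["SET01"]] + m2$eta[["DUP1"]], m1$eta[["SET01"]],
               tolerance = 1e-3)
})

test_that("select_gene_sets applies the threshold and counts unique genes", {
  h <- make_test_stack(n = 15, n_genes = 40, n_sets = 4)
  m <- prognosit_fit(h$stack, h$y, C = 1, epsilon = 0.25 * sd(h$y),
                     max_iter = 5)
  m$eta <- stats::setNames(c(0.99, 0.005, 0.005, 0), names(m$eta))
  sel <- select_gene_sets(m)
  expect_identical(sel$selected, names(m$eta)[1])
  expect_identical(sel$n_genes_used, length(h$partition$indices[[1]]))
  # sub-threshold uniform weights select nothing
  m$eta <- stats::setNames(rep(0.005, 4), names(m$eta))
  expect_identical(select_gene_sets(m)$n_selected, 0L)
  # union counts shared genes once
  m$eta <- stats::setNames(c(0.6, 0.4, 0, 0), names(m$eta))
  expect_identical(select_gene_sets(m)$n_genes_used,
                   length(unique(unlist(h$partition$indices[1:2]))))
})

test_that("model persistence round-trips predictions through JSON", {
  h <- make_test_stack(n = 20, n_genes = 40, n_sets = 4)
  m <- prognosit_fit(h$stack, h$y, C = 1, epsilon = 0.25 * sd(h$y),
                     max_iter = 20)
  path <- withr::local_tempfile(fileext = ".json")
  save_prognosit_model(m, path, standardizer = h$std)
  loaded <- load_prognosit_model(path)
  expect_equal(predict(loaded$model, h$x_std), predict(m, h$x_std),
               tolerance = 1e-10)
  expect_equal(loaded$standardizer$center, h$std$center, ignore_attr = TRUE)
})
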