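test_that("nrmse identities: mean predictor, perfect fit, affine invariance", {
  y <- c(0, 2)
  expect_equal(nrmse(y, c(1, 1)), 1)
  set.seed(1)
  yy <- rnorm(20)
  expect_equal(nrmse(yy, rep(mean(yy), 20)), 1)
  expect_equal(nrmse(yy, yy), 0)
  yhat <- yy + rnorm(20, 0, 0.3)
  expect_equal(nrmse(3.7 * yy - 2, 3.7 * yhat - 2), nrmse(yy, yhat),
               tolerance = 1e-12)
  expect_error(nrmse(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(nrmse(1:3, 1:4), "mismatch")
})

test_that("the default grid is 7 C values x 9 tube multipliers x 4 folds", {
  g <- hyper_grid()
  expect_equal(g$C, 10^seq(-3, 3))
  expect_equal(g$tube_multipliers, seq(0, 2, by = 0.25))
  expect_identical(g$n_folds, 4L)
  expect_error(hyper_grid(C = numeric(0)), "nonempty")
  expect_error(hyper_grid(C = c(-1, 1)), "positive")
})

small_cohort <- function(seed = 13, n = 28, n_genes = 12, n_sets = 2) {
  spec <- synthetic_spec(n_samples = n, n_genes = n_genes, n_sets = n_sets,
                         informative_sets = 1L, seed = seed)
  cohort <- generate_cohort(spec)
  list(x = cohort$expression, y = cube_root(cohort$volumes),
       partition = map_to_features(cohort$sets, colnames(cohort$expression)))
}

test_that("grid search evaluates every configuration in every fold", {
  sc <- small_cohort()
  g <- hyper_grid(C = c(0.1, 1), tube_multipliers = c(0.25, 1), n_folds = 3)
  gs <- grid_search(sc$x, sc$y, sc$partition, g, algorithm = "svr", seed = 5)
  expect_identical(nrow(gs$cv_folds), 2L * 2L * 3L)
  expect_identical(nrow(gs$cv_table), 4L)
  # epsilon really is multiplier x sd of the fold-training responses
  for (fold in 1:3) {
    y_tr <- sc$y[gs$folds != fold]
    rows <- gs$cv_folds[gs$cv_folds$fold == fold, ]
    expect_equal(rows$epsilon, rows$tube_multiplier * sd(y_tr))
  }
  # determinism under the seed
  gs2 <- grid_search(sc$x, sc$y, sc$partition, g, algorithm = "svr", seed = 5)
  expect_identical(gs2$C, gs$C)
  expect_identical(gs2$tube_multiplier, gs$tube_multiplier)
  expect_equal(gs2$cv_table, gs$cv_table)
})

test_that("grid-search ties break towards the smallest C then multiplier", {
  sc <- small_cohort()
  g <- hyper_grid(C = c(0.5, 2), tube_multipliers = c(0.1, 0.6), n_folds = 2)
  gs <- grid_search(sc$x, sc$y, sc$partition, g, algorithm = "svr", seed = 2)
  # force ties by hand on the aggregated table and re-apply the rule
  agg <- gs$cv_table
  agg$nrmse <- 0.5
  agg <- agg[order(agg$C, agg$tube_multiplier), ]
  best <- agg[which.min(agg$nrmse), ]
  expect_equal(best$C, 0.5)
  expect_equal(best$tube_multiplier, 0.1)
})

test_that("run_replications returns one scored row per replication", {
  sc <- small_cohort()
  g <- hyper_grid(C = 1, tube_multipliers = c(0.25, 0.5), n_folds = 2)
  res <- run_replications(sc$x, sc$y, sc$partition, g,
                          algorithm = "prognosit", n_reps = 3, base_seed = 7,
                          max_iter = 30)
  expect_identical(nrow(res$results), 3L)
  expect_true(all(res$results$nrmse >= 0, na.rm = TRUE))
  expect_true(all(is.na(res$results$error)))
  expect_identical(dim(res$eta), c(3L, 2L))
  # used genes never exceed the matched total
  expect_true(all(res$results$n_genes_used <= sc$partition$union_size))
  # reproducibility
  res2 <- run_replications(sc$x, sc$y, sc$partition, g,
                           algorithm = "prognosit", n_reps = 3, base_seed = 7,
                           max_iter = 30)
  expect_equal(res2$results, res$results)
})

test_that("selection frequencies count threshold crossings", {
  res <- structure(list(
    eta = rbind(c(0.9, 0.1, 0), c(0.8, 0.005, 0.195), c(1, 0, 0)),
    threshold = 0.01,
    results = data.frame(error = rep(NA_character_, 3))),
    class = "replication_results")
  colnames(res$eta) <- c("A", "B", "C")
  sf <- selection_frequencies(res)
  expect_identical(sf$frequencies$frequency, c(3L, 1L, 1L))
  expect_equal(sf$mean_selected, mean(c(2, 2, 1)))
})

test_that("paired Wilcoxon matches exact enumeration on small samples", {
  # all-positive, untied differences over 6 pairs: two-sided exact p = 2/64
  tum <- matrix(5:10 + (1:6) / 10, 1, dimnames = list("g1", paste0("s", 1:6)))
  nor <- matrix(5:10 - (1:6) / 10, 1, dimnames = list("g1", paste0("s", 1:6)))
  res <- paired_wilcoxon(tum, nor)
  expect_equal(res$p_value, 0.03125)
  expect_identical(res$direction, "up")
  # random continuous paired data, n <= 10: exact match to enumeration
  set.seed(17)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    t_row <- matrix(rnorm(n), 1, dimnames = list("g", paste0("s", 1:n)))
    n_row <- matrix(rnorm(n), 1, dimnames = list("g", paste0("s", 1:n)))
    expect_equal(paired_wilcoxon(t_row, n_row)$p_value,
                 oracle_signed_rank_p(drop(t_row - n_row)),
                 tolerance = 1e-12)
  }
})

test_that("identical tissues give no significance and a neutral direction", {
  x <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  res <- paired_wilcoxon(x, x)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$direction == "none"))
  expect_true(all(res$all_zero))
  expect_false(any(res$significant))
})

test_that("pairing is invariant to a consistent sample permutation", {
  set.seed(23)
  tum <- matrix(rnorm(60), 6, dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  nor <- matrix(rnorm(60), 6, dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  perm <- sample(10)
  expect_equal(paired_wilcoxon(tum[, perm], nor[, perm])$p_value,
               paired_wilcoxon(tum, nor)$p_value)
})

test_that("unpaired inputs are rejected with the mismatched samples named", {
  tum <- matrix(rnorm(10), 2, dimnames = list(c("g1", "g2"), paste0("s", 1:5)))
  nor <- tum
  colnames(nor) <- c(paste0("s", 1:4), "OTHER")
  expect_error(paired_wilcoxon(tum, nor), "s5")
  expect_error(paired_wilcoxon(tum[, 1:3], tum[, 1:3]), "at least 4")
})

test_that("BH adjustment is available behind a flag", {
  set.seed(29)
  tum <- matrix(rnorm(200), 20, dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  nor <- matrix(rnorm(200), 20, dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  res <- paired_wilcoxon(tum, nor, p_adjust = "BH")
  expect_true("p_adjusted" %in% names(res))
  expect_equal(res$p_adjusted, p.adjust(res$p_value, "BH"))
})

test_that("compare_algorithms runs a paired two-sided t-test", {
  set.seed(31)
  a <- rnorm(20, 0.8, 0.05)
  b <- a + rnorm(20, 0.05, 0.02)
  out <- compare_algorithms(a, b)
  expect_equal(out$p_value, t.test(a, b, paired = TRUE)$p.value)
  expect_identical(out$winner, "a")
})
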