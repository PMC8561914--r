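#' Normalized root mean squared error
#'
#' \deqn{\mathrm{NRMSE} = \sqrt{\frac{(y - \hat y)^\top (y - \hat y)}
#' {(y - \bar y \mathbf{1})^\top (y - \bar y \mathbf{1})}}.}
#' The mean predictor scores exactly 1; values below 1 mean the model learned
#' something from the data. The metric is invariant under a common affine
#' transform of `y` and `y_hat`.
#'
#' @param y Observed responses (length >= 2, not constant).
#' @param y_hat Predicted responses of the same length.
#' @return Non-negative scalar.
#' @export
nrmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 2L) stop("need at least 2 observations")
  denom <- sum((y - mean(y))^2)
  if (denom <= 0) stop("observed responses are constant; NRMSE undefined")
  sqrt(sum((y - y_hat)^2) / denom)
}

#' Hyperparameter grid for the cross-validated search
#'
#' Defaults are the protocol's grids: regularization
#' `C` in `{1e-3, 1e-2, ..., 1e+3}` (7 values) and tube-width multiplier in
#' `{0, 0.25, 0.5, ..., 2}` (9 values), searched with 4-fold cross-validation
#' on the training set. The multiplier, not epsilon itself, is tuned; at fit
#' time epsilon = multiplier x sd(current training responses).
#'
#' @param C Candidate regularization values.
#' @param tube_multipliers Candidate tube-width multipliers.
#' @param n_folds Number of cross-validation folds (default 4).
#' @return An object of class `hyper_grid`.
#' @export
hyper_grid <- function(C = 10^seq(-3, 3),
                       tube_multipliers = seq(0, 2, by = 0.25),
                       n_folds = 4L) {
  if (length(C) == 0L || length(tube_multipliers) == 0L) {
    stop("grids must be nonempty")
  }
  if (any(C <= 0)) stop("C values must be positive")
  if (any(tube_multipliers < 0)) stop("tube multipliers must be >= 0")
  if (n_folds < 2L) stop("need at least 2 folds")
  structure(list(C = sort(C), tube_multipliers = sort(tube_multipliers),
                 n_folds = as.integer(n_folds)),
            class = "hyper_grid")
}

# Internal single-set partition used by the all-features SVR baseline.
all_features_partition <- function(d) {
  structure(list(indices = list(ALL_FEATURES = seq_len(d)),
                 n_matched = c(ALL_FEATURES = d),
                 empty = character(0), union_size = d),
            class = "feature_partition")
}

# Standardize on the training part, build kernels, fit either the
# single-kernel SVR baseline or the pathway-MKL model, and predict on the
# held-out part. epsilon = tube multiplier x sd of the current training
# responses, recomputed here for every (sub)training set.
fit_and_predict <- function(x_tr, y_tr, x_ho, partition, algorithm,
                            C, tube_multiplier, max_iter = 200L,
                            eta_tol = 1e-6, threshold = 0.01) {
  std <- fit_standardizer(x_tr)
  x_tr_std <- apply_standardizer(std, x_tr)
  x_ho_std <- apply_standardizer(std, x_ho)
  epsilon <- tube_multiplier * stats::sd(y_tr)
  if (algorithm == "svr") partition <- all_features_partition(ncol(x_tr))
  stack <- suppressWarnings(build_kernel_stack(x_tr_std, partition))
  if (algorithm == "svr") {
    sol <- solve_svr_dual(stack$kernels[[1]], y_tr, C, epsilon)
    k_cross <- cross_kernel_stack(stack, x_ho_std)[[1]]
    list(pred = predict(sol, k_cross), model = sol, epsilon = epsilon,
         standardizer = std)
  } else {
    model <- suppressWarnings(
      prognosit_fit(stack, y_tr, C, epsilon, max_iter = max_iter,
                    eta_tol = eta_tol, threshold = threshold))
    list(pred = predict(model, x_ho_std), model = model, epsilon = epsilon,
         standardizer = std)
  }
}

#' Cross-validated hyperparameter search
#'
#' Evaluates every (C, tube multiplier) pair of the grid by k-fold
#' cross-validation on the training set only: within each fold, the
#' standardizer, the kernel widths and the tube width epsilon = multiplier x
#' sd(fold-training responses) are re-fitted on the fold's training part.
#' The pair minimizing the mean validation NRMSE wins; ties are broken
#' towards the smallest C, then the smallest multiplier.
#'
#' @param x_train Training expression matrix (samples x genes), raw scale.
#' @param y_train Training responses (cube-rooted volumes).
#' @param partition A `feature_partition` (ignored when `algorithm = "svr"`,
#'   which uses all features in a single kernel).
#' @param grid A `hyper_grid`.
#' @param algorithm `"prognosit"` (pathway MKL) or `"svr"` (single-kernel
#'   baseline).
#' @param seed Seed for the fold assignment.
#' @param max_iter,eta_tol,threshold Passed to [prognosit_fit()].
#' @return List of class `grid_search` with `C`, `tube_multiplier` (the
#'   chosen pair), `cv_table` (mean validation NRMSE per configuration),
#'   `cv_folds` (one row per configuration x fold, including the epsilon
#'   actually used), `folds` (the fold assignment) and `seed`.
#' @export
grid_search <- function(x_train, y_train, partition, grid = hyper_grid(),
                        algorithm = c("prognosit", "svr"), seed = 1L,
                        max_iter = 200L, eta_tol = 1e-6, threshold = 0.01) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(grid, "hyper_grid"))
  x_train <- as.matrix(x_train)
  n <- nrow(x_train)
  folds <- make_folds(n, grid$n_folds, seed)

  rows <- list()
  for (fold in seq_len(grid$n_folds)) {
    tr <- folds != fold
    va <- !tr
    for (C in grid$C) {
      for (mult in grid$tube_multipliers) {
        fp <- fit_and_predict(x_train[tr, , drop = FALSE], y_train[tr],
                              x_train[va, , drop = FALSE], partition,
                              algorithm, C, mult, max_iter = max_iter,
                              eta_tol = eta_tol, threshold = threshold)
        val <- if (stats::sd(y_train[va]) > 0) {
          nrmse(y_train[va], fp$pred)
        } else NA_real_
        rows[[length(rows) + 1L]] <-
          data.frame(C = C, tube_multiplier = mult, fold = fold,
                     epsilon = fp$epsilon, nrmse = val)
      }
    }
  }
  cv_folds <- do.call(rbind, rows)
  agg <- stats::aggregate(nrmse ~ C + tube_multiplier, data = cv_folds,
                          FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  # tie-break: smallest C, then smallest multiplier
  agg <- agg[order(agg$C, agg$tube_multiplier), , drop = FALSE]
  best <- agg[which.min(agg$nrmse), , drop = FALSE]
  structure(list(C = best$C, tube_multiplier = best$tube_multiplier,
                 cv_table = agg, cv_folds = cv_folds, folds = folds,
                 seed = seed, algorithm = algorithm),
            class = "grid_search")
}

#' Run the replicated train/test evaluation protocol
#'
#' Per replication r (seed = `base_seed + r`): draw an 80/20 split, run the
#' cross-validated grid search on the training part, refit on the full
#' training part at the chosen hyperparameters, and score the held-out part
#' with NRMSE. Responses are expected on the model scale already (volumes
#' cube-rooted upstream); expression standardization always uses training
#' statistics only. A failing replication is recorded and the run continues.
#'
#' @inheritParams grid_search
#' @param x Full expression matrix (samples x genes).
#' @param y Full response vector.
#' @param n_reps Number of replications (the full protocol uses 100).
#' @param base_seed Base seed; replication r uses `base_seed + r`.
#' @param train_frac Training fraction of each split (default 0.8).
#' @return Object of class `replication_results`: a list with `results` (one
#'   row per replication: seed, chosen hyperparameters, test NRMSE, number of
#'   selected sets, used-gene count, error message if any), `eta`
#'   (replications x sets matrix of final kernel weights, `NULL` for the SVR
#'   baseline), `selected` (list of selected set names per replication),
#'   `algorithm`, `threshold`, `set_names`.
#' @export
run_replications <- function(x, y, partition, grid = hyper_grid(),
                             algorithm = c("prognosit", "svr"),
                             n_reps = 100L, base_seed = 0L, train_frac = 0.8,
                             max_iter = 200L, eta_tol = 1e-6,
                             threshold = 0.01) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  set_names <- names(partition$indices)
  eta_mat <- if (algorithm == "prognosit") {
    matrix(NA_real_, n_reps, length(set_names),
           dimnames = list(NULL, set_names))
  } else NULL
  selected_list <- vector("list", n_reps)
  rows <- vector("list", n_reps)

  for (r in seq_len(n_reps)) {
    seed <- base_seed + r
    rows[[r]] <- tryCatch({
      split <- make_split(nrow(x), seed, train_frac)
      gs <- grid_search(x[split$train, , drop = FALSE], y[split$train],
                        partition, grid, algorithm, seed = seed,
                        max_iter = max_iter, eta_tol = eta_tol,
                        threshold = threshold)
      fp <- fit_and_predict(x[split$train, , drop = FALSE], y[split$train],
                            x[split$test, , drop = FALSE], partition,
                            algorithm, gs$C, gs$tube_multiplier,
                            max_iter = max_iter, eta_tol = eta_tol,
                            threshold = threshold)
      test_nrmse <- nrmse(y[split$test], fp$pred)
      if (algorithm == "prognosit") {
        eta_mat[r, names(fp$model$eta)] <- fp$model$eta
        selected_list[[r]] <- fp$model$selected
        n_sel <- length(fp$model$selected)
        n_genes <- fp$model$n_genes_used
      } else {
        n_sel <- NA_integer_
        n_genes <- ncol(x)
      }
      data.frame(replication = r, seed = seed, C = gs$C,
                 tube_multiplier = gs$tube_multiplier, nrmse = test_nrmse,
                 n_selected = n_sel, n_genes_used = n_genes,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(replication = r, seed = seed, C = NA_real_,
                 tube_multiplier = NA_real_, nrmse = NA_real_,
                 n_selected = NA_integer_, n_genes_used = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  structure(list(results = do.call(rbind, rows), eta = eta_mat,
                 selected = selected_list, algorithm = algorithm,
                 threshold = threshold, set_names = set_names),
            class = "replication_results")
}

#' @export
print.replication_results <- function(x, ...) {
  ok <- is.na(x$results$error)
  cat("Replication results (", x$algorithm, "): ", sum(ok), "/",
      nrow(x$results), " succeeded, median test NRMSE = ",
      format(stats::median(x$results$nrmse[ok]), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Gene-set selection frequencies across replications
#'
#' Counts, for every gene set, the replications in which its final kernel
#' weight exceeded the selection threshold, and reports the mean number of
#' selected sets per replication.
#'
#' @param results A `replication_results` from a `"prognosit"` run.
#' @param threshold Selection threshold; defaults to the one used at fit
#'   time.
#' @return List with `frequencies` (data frame: set, frequency, n_reps) and
#'   `mean_selected` (mean per-replication selected-set count).
#' @export
selection_frequencies <- function(results, threshold = NULL) {
  stopifnot(inherits(results, "replication_results"))
  if (is.null(results$eta)) {
    stop("selection frequencies require a pathway-MKL run")
  }
  if (is.null(threshold)) threshold <- results$threshold
  ok <- rowSums(!is.na(results$eta)) > 0
  sel <- results$eta[ok, , drop = FALSE] > threshold
  freq <- colSums(sel)
  list(frequencies = data.frame(set = colnames(results$eta),
                                frequency = as.integer(freq),
                                n_reps = sum(ok), row.names = NULL,
                                stringsAsFactors = FALSE),
       mean_selected = mean(rowSums(sel)))
}

#' Paired Wilcoxon tumour-versus-normal differential analysis
#'
#' For every gene, a two-sided Wilcoxon signed-rank test compares the
#' expression in tumour tissue against the normal tissue of the same
#' patients. Zero paired differences are dropped (Wilcoxon's original
#' treatment); the exact null distribution is used for up to `exact_limit`
#' nonzero pairs when there are no ties, the normal approximation with
#' continuity correction otherwise. Direction is the sign of the median
#' paired difference. Significance is called at raw p < `alpha`, matching
#' the protocol; Benjamini-Hochberg adjustment is available as an option.
#'
#' @param tumour,normal Numeric matrices, genes x paired samples, with
#'   identical row (gene) and column (sample) labels.
#' @param alpha Significance level (default 0.05).
#' @param exact_limit Largest number of nonzero pairs for which the exact
#'   distribution is used (default 25).
#' @param p_adjust `"none"` (default) or `"BH"`; with `"BH"` the significance
#'   flag uses the adjusted p-values.
#' @return Data frame with one row per gene: `gene`, `median_diff`,
#'   `direction` (`"up"` when tumour > normal, `"down"`, `"none"`),
#'   `p_value`, optionally `p_adjusted`, `significant`, `all_zero`.
#' @export
paired_wilcoxon <- function(tumour, normal, alpha = 0.05, exact_limit = 25L,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  tumour <- as.matrix(tumour); normal <- as.matrix(normal)
  if (!is.null(colnames(tumour)) && !is.null(colnames(normal))) {
    missing_n <- setdiff(colnames(tumour), colnames(normal))
    missing_t <- setdiff(colnames(normal), colnames(tumour))
    if (length(missing_n) || length(missing_t)) {
      stop("unpaired samples - missing from normal: ",
           paste(missing_n, collapse = ", "), "; missing from tumour: ",
           paste(missing_t, collapse = ", "))
    }
    normal <- normal[, colnames(tumour), drop = FALSE]
  }
  if (!identical(dim(tumour), dim(normal))) {
    stop("tumour and normal matrices must have identical shape")
  }
  if (!is.null(rownames(tumour)) && !is.null(rownames(normal)) &&
      !identical(rownames(tumour), rownames(normal))) {
    stop("tumour and normal matrices must list the same genes in the same order")
  }
  n_pairs <- ncol(tumour)
  if (n_pairs < 4L) stop("need at least 4 paired samples")

  genes <- rownames(tumour)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(tumour)))
  d <- tumour - normal
  res <- lapply(seq_len(nrow(tumour)), function(g) {
    dg <- d[g, ]
    nz <- sum(dg != 0)
    if (nz == 0L) {
      return(data.frame(gene = genes[g], median_diff = 0,
                        direction = "none", p_value = 1, all_zero = TRUE,
                        stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(stats::wilcox.test(
      tumour[g, ], normal[g, ], paired = TRUE,
      exact = nz <= exact_limit, correct = TRUE)$p.value)
    md <- stats::median(dg)
    data.frame(gene = genes[g], median_diff = md,
               direction = if (md > 0) "up" else if (md < 0) "down" else "none",
               p_value = p, all_zero = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha & !out$all_zero
  } else {
    out$significant <- out$p_value < alpha & !out$all_zero
  }
  out
}

#' Paired t-test between two algorithms' replication scores
#'
#' Reporting utility for comparing per-replication NRMSE values of two
#' algorithms run on the same splits (two-tailed, paired).
#'
#' @param nrmse_a,nrmse_b Equal-length numeric vectors of per-replication
#'   scores.
#' @return List with `p_value`, `mean_diff` (a minus b) and `winner`.
#' @export
compare_algorithms <- function(nrmse_a, nrmse_b) {
  stopifnot(length(nrmse_a) == length(nrmse_b), length(nrmse_a) >= 2L)
  tt <- stats::t.test(nrmse_a, nrmse_b, paired = TRUE)
  list(p_value = tt$p.value, mean_diff = mean(nrmse_a - nrmse_b),
       winner = if (mean(nrmse_a) < mean(nrmse_b)) "a" else "b")
}
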