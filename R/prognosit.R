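#' Initialize kernel weights on the unit simplex
#'
#' All P kernels start with equal weight 1/P.
#'
#' @param p Number of kernels (P >= 1).
#' @return Numeric vector of length `p`, each entry `1/p`.
#' @export
init_eta <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1) stop("P must be >= 1")
  rep(1 / p, p)
}

#' Multiplicative kernel-weight update
#'
#' One step of the group-Lasso-style update used between SVR solves:
#' \deqn{\eta_m' = \frac{\eta_m \sqrt{\alpha^\top K_m \alpha}}
#' {\sum_o \eta_o \sqrt{\alpha^\top K_o \alpha}},}
#' with \eqn{\alpha = \alpha^+ - \alpha^-} from the current dual solution.
#' The update keeps the weights on the unit simplex, is invariant to a
#' positive rescaling of `alpha`, and has absorbing zeros: a weight that is
#' exactly 0 stays 0. Quadratic forms that round off slightly negative are
#' clamped to 0 before the square root. Entries below `floor` are snapped to
#' exactly 0 and the vector renormalized.
#'
#' @param eta Current simplex weights.
#' @param alpha Combined dual coefficients `alpha_plus - alpha_minus`.
#' @param kernels A `kernel_stack` or list of training kernel matrices.
#' @param floor Weights below this are set to 0 (default 1e-12).
#' @return Updated weight vector. If every quadratic form is 0 (the all-zero
#'   `alpha` of a degenerate, constant model) the input `eta` is returned
#'   unchanged with attribute `degenerate = TRUE`.
#' @export
update_eta <- function(eta, alpha, kernels, floor = 1e-12) {
  klist <- if (inherits(kernels, "kernel_stack")) kernels$kernels else kernels
  if (length(eta) != length(klist)) stop("eta/kernel length mismatch")
  q <- unname(vapply(klist, function(K) {
    v <- drop(crossprod(alpha, K %*% alpha))
    sqrt(max(v, 0))
  }, numeric(1)))
  denom <- sum(eta * q)
  if (denom <= 0) {
    attr(eta, "degenerate") <- TRUE
    return(eta)
  }
  out <- eta * q / denom
  out[out < floor] <- 0
  out / sum(out)
}

#' Fit the pathway-MKL support vector regression model
#'
#' Alternates between (i) solving the epsilon-SVR dual on the current convex
#' kernel combination and (ii) the closed-form multiplicative weight update,
#' starting from uniform weights. The dual objective decreases monotonically
#' across iterations; the loop stops after `max_iter` iterations (default
#' 200, which in practice is far past convergence) or as soon as the L1
#' change of the weights falls below `eta_tol`. The reported solution is
#' re-solved once at the final weights so that coefficients and weights are
#' mutually optimal.
#'
#' @param stack A `kernel_stack` of training kernels.
#' @param y Training responses (already cube-rooted upstream when they are
#'   volumes).
#' @param C Positive regularization parameter.
#' @param epsilon Non-negative tube half-width.
#' @param max_iter Maximum number of alternations (default 200).
#' @param eta_tol Stop when `sum(abs(eta_new - eta_old)) < eta_tol`
#'   (default 1e-6).
#' @param threshold Kernel-weight selection threshold (default 0.01): sets
#'   with a final weight above it are reported as selected.
#' @param jitter,tol Passed to [solve_svr_dual()].
#' @return An object of class `prognosit_model` with fields `eta` (named
#'   final weights), `solution` (`svr_solution` at the final weights),
#'   `trace` (data frame with per-iteration dual objective and weight
#'   change), `eta_trace` (iterations x P matrix of weights after each
#'   update), `selected`, `n_genes_used`, `stack`, `threshold`, `converged`,
#'   `degenerate`.
#' @export
prognosit_fit <- function(stack, y, C, epsilon, max_iter = 200L,
                          eta_tol = 1e-6, threshold = 0.01,
                          jitter = 1e-8, tol = 1e-8) {
  stopifnot(inherits(stack, "kernel_stack"))
  p <- length(stack$kernels)
  n <- nrow(stack$kernels[[1]])
  if (length(y) != n) stop("length(y) must match the kernel dimension")
  if (max_iter < 1L) stop("max_iter must be >= 1")

  eta <- init_eta(p)
  objective <- numeric(0)
  eta_change <- numeric(0)
  eta_trace <- matrix(NA_real_, 0L, p, dimnames = list(NULL, stack$set_names))
  degenerate <- FALSE
  converged <- FALSE
  sol <- NULL

  for (it in seq_len(max_iter)) {
    K_eta <- combine_kernels(stack, eta)
    sol <- solve_svr_dual(K_eta, y, C, epsilon, jitter = jitter, tol = tol,
                          beta0 = if (!is.null(sol)) sol$alpha)
    objective[it] <- sol$objective
    eta_new <- update_eta(eta, sol$alpha, stack)
    if (isTRUE(attr(eta_new, "degenerate"))) {
      warning("all dual coefficients are zero (tube covers the data); ",
              "keeping current kernel weights and stopping")
      degenerate <- TRUE
      eta_change[it] <- 0
      eta_trace <- rbind(eta_trace, eta)
      break
    }
    eta_change[it] <- sum(abs(eta_new - eta))
    eta_trace <- rbind(eta_trace, eta_new)
    eta <- eta_new
    if (eta_change[it] < eta_tol) {
      converged <- TRUE
      break
    }
  }

  # final re-solve, cold-started so the result is identical to a direct
  # solve_svr_dual call on the combined kernel (alpha and eta then come out
  # mutually optimal)
  sol <- solve_svr_dual(combine_kernels(stack, eta), y, C, epsilon,
                        jitter = jitter, tol = tol)
  names(eta) <- stack$set_names
  selected <- stack$set_names[eta > threshold]
  n_genes_used <- length(unique(unlist(stack$indices[selected])))

  structure(list(eta = eta, solution = sol,
                 trace = data.frame(iteration = seq_along(objective),
                                    objective = objective,
                                    eta_change = eta_change),
                 eta_trace = eta_trace,
                 selected = selected, n_genes_used = n_genes_used,
                 stack = stack, threshold = threshold,
                 C = C, epsilon = epsilon,
                 converged = converged, degenerate = degenerate),
            class = "prognosit_model")
}

#' Predict tumour volumes (on the transformed scale) for new samples
#'
#' Builds the per-set cross-kernels with the training-time widths, combines
#' them with the fitted weights and applies the kernel expansion
#' \eqn{\hat y_t = \sum_i \alpha_i K_\eta(t, i) + b}.
#'
#' @param object A `prognosit_model`.
#' @param x_new_std New samples, standardized with the training statistics.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.prognosit_model <- function(object, x_new_std, ...) {
  cross <- cross_kernel_stack(object$stack, x_new_std)
  k_eta <- combine_kernels(cross, as.numeric(object$eta))
  predict(object$solution, k_eta)
}

#' Report selected gene sets and the genes they use
#'
#' A set is selected when its final kernel weight exceeds the threshold; the
#' used-gene count is the size of the union of matched genes over selected
#' sets.
#'
#' @param model A `prognosit_model`.
#' @param threshold Selection threshold (default 0.01).
#' @return List with `selected` (set names), `n_selected`, `n_genes_used`.
#' @export
select_gene_sets <- function(model, threshold = 0.01) {
  stopifnot(inherits(model, "prognosit_model"))
  selected <- names(model$eta)[model$eta > threshold]
  list(selected = selected,
       n_selected = length(selected),
       n_genes_used = length(unique(unlist(model$stack$indices[selected]))))
}

#' @export
print.prognosit_model <- function(x, ...) {
  cat("Pathway-MKL SVR model: ", length(x$eta), " kernels, ",
      length(x$selected), " selected (weight > ", x$threshold, ")\n",
      sep = "")
  cat("  iterations:", nrow(x$trace),
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  top <- sort(x$eta, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5L, sum(x$eta > 0)))]
  cat("  top weights:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
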