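#' Solve the epsilon-insensitive SVR dual problem
#'
#' Minimizes the kernelized dual objective
#' \deqn{-\sum_i y_i(\alpha_i^+ - \alpha_i^-) + \epsilon \sum_i (\alpha_i^+ +
#' \alpha_i^-) + \tfrac{1}{2}\sum_{ij} (\alpha_i^+ - \alpha_i^-)
#' (\alpha_j^+ - \alpha_j^-) K_{ij}}
#' subject to \eqn{0 \le \alpha_i^\pm \le C} and
#' \eqn{\sum_i (\alpha_i^+ - \alpha_i^-) = 0}. The problem is posed in the 2N
#' variables \eqn{(\alpha^+; \alpha^-)} with block Hessian
#' `[[K, -K], [-K, K]]` plus a small ridge jitter (the block matrix is
#' positive semidefinite but singular, and the active-set solver needs a
#' factorizable matrix), and handed to [quadprog::solve.QP()]. The returned
#' pair is canonicalized through \eqn{\beta = \alpha^+ - \alpha^-},
#' \eqn{\alpha^+ = \max(\beta, 0)}, \eqn{\alpha^- = \max(-\beta, 0)}: this
#' preserves feasibility and the quadratic/linear terms (which depend on
#' \eqn{\beta} only), can only shrink the \eqn{\epsilon} term, and makes the
#' complementarity \eqn{\alpha_i^+ \alpha_i^- = 0} exact.
#'
#' @param K Symmetric positive-semidefinite N x N kernel matrix.
#' @param y Length-N response vector.
#' @param C Positive regularization parameter.
#' @param epsilon Non-negative tube half-width. In the evaluation protocol
#'   this is the tuned tube-width multiplier times the standard deviation of
#'   the current training responses.
#' @param jitter Ridge added to the dual Hessian diagonal (default 1e-8).
#' @param tol Tolerance used for support-vector classification when
#'   recovering the intercept (default 1e-8).
#' @param beta0 Optional feasible warm start for the combined coefficients
#'   (used by the SMO backend; the iterative MKL loop passes the previous
#'   iteration's solution).
#' @return An object of class `svr_solution` with fields `alpha_plus`,
#'   `alpha_minus`, `alpha` (their difference), `b` (intercept), `objective`
#'   (dual objective value at the solution), `C`, `epsilon`.
#' @references The base learner is the classical epsilon-SVR dual; the
#'   intercept is recovered from the Karush-Kuhn-Tucker conditions.
#' @export
solve_svr_dual <- function(K, y, C, epsilon, jitter = 1e-8, tol = 1e-8,
                           beta0 = NULL) {
  K <- as.matrix(K)
  n <- length(y)
  if (nrow(K) != n || ncol(K) != n) stop("K must be N x N with N = length(y)")
  if (anyNA(K) || anyNA(y) || any(!is.finite(K)) || any(!is.finite(y))) {
    stop("NaN or non-finite values in K or y")
  }
  if (max(abs(K - t(K))) > 1e-8) stop("K must be symmetric")
  if (!is.numeric(C) || length(C) != 1L || C <= 0) stop("C must be positive")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    stop("epsilon must be non-negative")
  }

  # The dual Hessian [[K, -K], [-K, K]] is always rank-deficient, and
  # mean-distance-width Gaussian kernels are themselves near-singular, which
  # can make the dense active-set solver fail outright or - worse - return a
  # silently infeasible point. Every candidate solution is therefore
  # verified (box and equality feasibility of the raw iterate, then the
  # primal-dual gap after canonicalization) before it is accepted; on
  # failure the next, more robust solver in the chain takes over:
  # quadprog (fast) -> ipop (interior point) -> accelerated projected
  # gradient (slow but unconditionally convergent).
  backends <- list(
    quadprog = function() svr_qp_quadprog(K, y, C, epsilon, jitter),
    ipop = function() svr_qp_ipop(K, y, C, epsilon, jitter),
    eqsolve = function() svr_qp_eqsolve(K, y, C, epsilon, jitter),
    smo = function() svr_qp_smo(K, y, C, epsilon, beta0 = beta0)
  )
  # with a warm start the SMO solver usually finishes in a handful of pair
  # updates, so it is promoted ahead of the interior-point solver
  order <- if (is.null(beta0)) c("quadprog", "ipop", "eqsolve", "smo")
           else c("quadprog", "smo", "ipop", "eqsolve")
  candidates <- backends[order]
  solver_names <- order
  accepted <- NULL
  for (s in seq_along(candidates)) {
    a <- tryCatch(candidates[[s]](), error = function(e) NULL)
    if (is.null(a)) next
    chk <- svr_check_solution(a, K, y, C, epsilon)
    if (chk$ok) {
      accepted <- chk
      solver <- solver_names[s]
      break
    }
  }
  if (is.null(accepted)) {
    stop("no QP solver produced a verified solution ",
         "(N = ", n, ", C = ", C, ", epsilon = ", epsilon, ")")
  }
  beta <- accepted$beta
  alpha_plus <- pmax(beta, 0)
  alpha_minus <- pmax(-beta, 0)

  b <- svr_intercept(alpha_plus, alpha_minus, K, y, C, epsilon, tol = tol)
  obj <- svr_dual_objective(alpha_plus, alpha_minus, K, y, epsilon)
  structure(list(alpha_plus = alpha_plus, alpha_minus = alpha_minus,
                 alpha = beta, b = b, objective = obj,
                 C = C, epsilon = epsilon, tol = tol,
                 solver = solver, gap = accepted$gap),
            class = "svr_solution")
}

# --- internal QP back ends -------------------------------------------------

svr_qp_quadprog <- function(K, y, C, epsilon, jitter) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + jitter * diag(2L * n)
  dvec <- -c(-y + epsilon, y + epsilon)   # solve.QP minimizes -d'x + x'Hx/2
  sgn <- c(rep(1, n), rep(-1, n))
  Amat <- cbind(sgn, diag(2L * n), -diag(2L * n))
  bvec <- c(0, rep(0, 2L * n), rep(-C, 2L * n))
  quadprog::solve.QP(H, dvec, Amat, bvec, meq = 1L)$solution
}

svr_qp_ipop <- function(K, y, C, epsilon, jitter) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + jitter * diag(2L * n)
  sgn <- c(rep(1, n), rep(-1, n))
  ip <- kernlab::ipop(c = c(-y + epsilon, y + epsilon), H = H,
                      A = matrix(sgn, 1L), b = 0, l = rep(0, 2L * n),
                      u = rep(C, 2L * n), r = 0, sigf = 9, maxiter = 120)
  kernlab::primal(ip)
}

# With epsilon = 0 and no box constraint active, stationarity reduces to the
# equality-constrained linear system [[K + jitter*I, 1], [1', 0]] (beta; b) =
# (y; 0) - ridge-regression-with-intercept form. Valid whenever the solution
# respects the box, which the verification step confirms; mainly rescues the
# large-C, zero-tube corner where the box never binds.
svr_qp_eqsolve <- function(K, y, C, epsilon, jitter) {
  if (epsilon > 0) stop("eqsolve backend applies only to epsilon = 0")
  n <- length(y)
  # the ridge bias leaves residuals ~ jitter * |beta|, which the primal term
  # multiplies by C, so shrink the ridge as C grows
  jitter <- max(min(jitter, 1e-10 / C), 1e-14)
  A <- rbind(cbind(K + jitter * diag(n), rep(1, n)), c(rep(1, n), 0))
  sol <- solve(A, c(y, 0))
  beta <- sol[1:n]
  if (max(abs(beta)) > C) stop("box constraint active; eqsolve inapplicable")
  c(pmax(beta, 0), pmax(-beta, 0))
}

# Sequential minimal optimization in the beta = alpha+ - alpha- coordinates:
# repeatedly pick the maximal violating pair (i moved up, j moved down, which
# preserves sum(beta) = 0) and minimize the piecewise-quadratic objective
# exactly along that direction, accounting for the epsilon-term kinks where
# beta crosses 0. Needs no matrix factorization, so it is robust to
# near-singular kernels; accepts a feasible warm start.
svr_qp_smo <- function(K, y, C, epsilon, beta0 = NULL,
                       viol_tol = NULL, max_iter = 400000L) {
  n <- length(y)
  # the duality gap is bounded by roughly viol * 2n * C, so the stopping
  # tolerance must shrink as C grows for the verification to pass
  if (is.null(viol_tol)) viol_tol <- max(min(1e-9, 5e-9 / (n * C)), 1e-13)
  beta <- if (is.null(beta0)) rep(0, n) else pmin(pmax(beta0, -C), C)
  if (abs(sum(beta)) > 1e-12) beta <- beta - sum(beta) / n
  beta <- pmin(pmax(beta, -C), C)
  g <- drop(K %*% beta)
  kdiag <- diag(K)
  for (it in seq_len(max_iter)) {
    r <- g - y
    # marginal cost of increasing / decreasing each beta_i by +t
    up_rate <- r + ifelse(beta >= 0, epsilon, -epsilon)
    dn_rate <- -r + ifelse(beta <= 0, epsilon, -epsilon)
    up_rate[beta >= C] <- Inf
    dn_rate[beta <= -C] <- Inf
    # second-order working-set selection: lead with the most violating
    # coordinate on either side, partner chosen by maximal gain b^2 / (2q)
    iu <- which.min(up_rate)
    id <- which.min(dn_rate)
    if (!is.finite(up_rate[iu]) || !is.finite(dn_rate[id])) break
    viol <- -(up_rate[iu] + dn_rate[id])
    if (viol <= viol_tol) break
    pick_partner <- function(lead, lead_rate, other_rate) {
      cand <- which(other_rate < -lead_rate)
      cand <- cand[cand != lead]
      if (length(cand) == 0L) return(NULL)
      qv <- pmax(kdiag[cand] + kdiag[lead] - 2 * K[cand, lead], 1e-12)
      bv <- -(lead_rate + other_rate[cand])
      gain <- bv^2 / qv
      list(j = cand[which.max(gain)], gain = max(gain))
    }
    p_up <- pick_partner(iu, up_rate[iu], dn_rate)
    p_dn <- pick_partner(id, dn_rate[id], up_rate)
    if (is.null(p_up) && is.null(p_dn)) break
    if (is.null(p_dn) || (!is.null(p_up) && p_up$gain >= p_dn$gain)) {
      i <- iu; j <- p_up$j
    } else {
      i <- p_dn$j; j <- id
    }
    t_max <- min(C - beta[i], beta[j] + C)
    if (t_max <= 0) break
    q <- K[i, i] + K[j, j] - 2 * K[i, j]
    # breakpoints where the epsilon term changes slope
    bps <- c(if (beta[i] < 0) -beta[i], if (beta[j] > 0) beta[j])
    bps <- sort(unique(c(bps[bps > 0 & bps < t_max], t_max)))
    lo <- 0
    t_step <- t_max
    for (hi in bps) {
      mid <- (lo + hi) / 2
      slope_lo <- q * lo + (r[i] - r[j]) +
        epsilon * (sign(beta[i] + mid) - sign(beta[j] - mid))
      slope_hi <- q * hi + (r[i] - r[j]) +
        epsilon * (sign(beta[i] + mid) - sign(beta[j] - mid))
      if (slope_hi >= 0) {
        t_step <- if (slope_lo >= 0) lo
                  else if (q > 0) lo + (-slope_lo) / q
                  else hi
        break
      }
      lo <- hi
      t_step <- hi
    }
    if (t_step <= 0) break
    beta[i] <- beta[i] + t_step
    beta[j] <- beta[j] - t_step
    g <- g + t_step * (K[, i] - K[, j])
    if (it %% 20000L == 0L) g <- drop(K %*% beta)  # curb incremental drift
  }
  c(pmax(beta, 0), pmax(-beta, 0))
}

# Verify a raw 2N iterate: box/equality feasibility, then the primal-dual
# gap of the canonicalized point (beta = alpha+ - alpha-). Returns the
# canonical beta so accepted solutions are exactly feasible.
svr_check_solution <- function(a, K, y, C, epsilon,
                               feas_tol = 1e-6, gap_tol = 1e-6) {
  n <- length(y)
  ap <- a[1:n]; am <- a[(n + 1):(2L * n)]
  box_viol <- max(0, -min(ap), -min(am), max(ap) - C, max(am) - C)
  eq_viol <- abs(sum(ap) - sum(am))
  if (box_viol > feas_tol || eq_viol > feas_tol) {
    return(list(ok = FALSE, gap = Inf, beta = NULL))
  }
  beta <- pmin(pmax(ap - am, -C), C)
  beta <- beta - mean(beta)            # re-center the tiny equality residual
  beta <- pmin(pmax(beta, -C), C)
  g <- drop(K %*% beta)
  # gap against the best primal completion of beta: the intercept minimizing
  # the epsilon-insensitive loss (piecewise linear and convex in b, so the
  # minimum sits on a breakpoint r_i +/- epsilon)
  r <- y - g
  bps <- c(r - epsilon, r + epsilon)
  loss <- vapply(bps, function(b) sum(pmax(abs(r - b) - epsilon, 0)),
                 numeric(1))
  dual <- -svr_dual_objective(pmax(beta, 0), pmax(-beta, 0), K, y, epsilon)
  primal <- 0.5 * drop(crossprod(beta, g)) + C * min(loss)
  gap <- primal - dual
  list(ok = gap <= gap_tol * max(1, abs(primal)), gap = gap, beta = beta)
}

#' Intercept recovery from the KKT conditions
#'
#' Each sample bounds the intercept through the tube constraints: a sample
#' with \eqn{\alpha_i^+ < C} enforces \eqn{b \ge y_i - g_i - \epsilon} (with
#' \eqn{g_i = \sum_j \alpha_j K_{ij}}), one with \eqn{\alpha_i^+ > 0} enforces
#' \eqn{b \le y_i - g_i - \epsilon}, and symmetrically for \eqn{\alpha^-}.
#' Free support vectors (strictly inside the box) pin the intercept exactly
#' and are averaged; when none exist the midpoint of the implied feasible
#' interval is returned (for the all-zero solution this is the midpoint of
#' `[max(y) - epsilon, min(y) + epsilon]`).
#'
#' @inheritParams solve_svr_dual
#' @param alpha_plus,alpha_minus Dual coefficient vectors.
#' @return Scalar intercept `b`.
#' @export
svr_intercept <- function(alpha_plus, alpha_minus, K, y, C, epsilon,
                          tol = 1e-8) {
  g <- drop(K %*% (alpha_plus - alpha_minus))
  r <- y - g
  # classification must be coarser than solver noise: verified solutions can
  # carry coefficients ~1e-7 off an active bound, and a bound SV mistaken
  # for a free one contributes a badly wrong pinned equation to the mean
  thr <- max(tol, 1e-5 * C)
  free_p <- alpha_plus > thr & alpha_plus < C - thr
  free_m <- alpha_minus > thr & alpha_minus < C - thr
  if (any(free_p) || any(free_m)) {
    return(mean(c(r[free_p] - epsilon, r[free_m] + epsilon)))
  }
  lower <- c(r[alpha_plus < C - thr] - epsilon, r[alpha_minus > thr] + epsilon)
  upper <- c(r[alpha_plus > thr] - epsilon, r[alpha_minus < C - thr] + epsilon)
  lo <- if (length(lower)) max(lower) else -Inf
  hi <- if (length(upper)) min(upper) else Inf
  if (!is.finite(lo) && !is.finite(hi)) return(mean(r))
  if (!is.finite(lo)) return(hi)
  if (!is.finite(hi)) return(lo)
  (lo + hi) / 2
}

#' Evaluate the SVR dual objective
#'
#' Pure evaluation of the dual objective at a given coefficient pair; the MKL
#' loop records this value at every iteration to verify its monotone
#' decrease.
#'
#' @inheritParams svr_intercept
#' @return Scalar objective value (0 at the all-zero solution).
#' @export
svr_dual_objective <- function(alpha_plus, alpha_minus, K, y, epsilon) {
  beta <- alpha_plus - alpha_minus
  -sum(y * beta) + epsilon * sum(alpha_plus + alpha_minus) +
    0.5 * drop(crossprod(beta, K %*% beta))
}

#' Predict from a fitted SVR dual solution
#'
#' @param object An `svr_solution`.
#' @param k_cross M x N cross-kernel matrix between the M prediction samples
#'   (rows) and the N training samples (columns).
#' @param ... Unused.
#' @return Numeric vector of M predictions
#'   \eqn{\hat y_t = \sum_i \alpha_i K(t, i) + b}.
#' @export
predict.svr_solution <- function(object, k_cross, ...) {
  k_cross <- as.matrix(k_cross)
  if (ncol(k_cross) != length(object$alpha)) {
    stop("cross-kernel has ", ncol(k_cross), " columns but the model has ",
         length(object$alpha), " training samples")
  }
  unname(drop(k_cross %*% object$alpha)) + object$b
}

#' @export
print.svr_solution <- function(x, ...) {
  cat("epsilon-SVR dual solution: N =", length(x$alpha),
      " SVs =", sum(abs(x$alpha) > x$tol),
      " b =", format(x$b, digits = 4),
      " objective =", format(x$objective, digits = 6), "\n")
  invisible(x)
}
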