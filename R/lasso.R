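#' Solve one weighted adaptive-LASSO subproblem on the probability simplex
#'
#' Minimizes sum_k w_k ||p_k - A_k alpha||^2 + lam * c' alpha subject to
#' alpha >= 0, sum(alpha) = 1 (on the nonnegative orthant the weighted L1
#' penalty is the linear form c' alpha, so the problem is a convex QP).
#'
#' The solver is a primal log-barrier interior-point method: for a
#' decreasing barrier parameter mu it takes equality-constrained Newton
#' steps on f(alpha) - mu * sum(log alpha) over the hyperplane
#' sum(alpha) = 1.  The Hessian is diagonal-plus-low-rank (the stacked
#' design has only 4K + 3 rows), so each Newton system is solved through
#' the Woodbury identity at O(R^2 N_B) cost, which keeps ~46k-coefficient
#' problems fast.  The method is deterministic: fixed starting point
#' (uniform), fixed barrier schedule, no randomness.
#'
#' @param system a [constraint_system].
#' @param lam penalty strength lambda > 0.
#' @param c_weights strictly positive per-coefficient weights (default all
#'   ones).
#' @param control list of solver settings: `gap_tol` (target barrier
#'   suboptimality bound mu * N_B, default 1e-9), `mu_shrink` (barrier
#'   reduction factor, default 20), `max_newton` per barrier stage
#'   (default 60), `newton_tol` (Newton decrement threshold, 1e-12).
#' @param stacked optional precomputed [stack_system] result (an internal
#'   reuse hook for the outer reweighting loop).
#' @return List with `alpha` (feasible to ~1e-9), `objective`,
#'   `iterations` (total Newton steps), and `status` ("optimal").
#' @export
solve_weighted_lasso <- function(system, lam, c_weights = NULL,
                                 control = list(), stacked = NULL) {
  stopifnot(inherits(system, "constraint_system"), lam > 0)
  nb <- system$basis$basis_count
  if (is.null(c_weights)) c_weights <- rep(1, nb)
  if (length(c_weights) != nb || any(c_weights <= 0))
    stopf("solve_weighted_lasso: c_weights must be %d positive values", nb)
  gap_tol <- control$gap_tol %||% 1e-9
  mu_shrink <- control$mu_shrink %||% 20
  max_newton <- control$max_newton %||% 60L
  newton_tol <- control$newton_tol %||% 1e-12
  if (is.null(stacked)) stacked <- stack_system(system)
  B <- stacked$B; q <- stacked$q
  lin <- lam * c_weights

  fval <- function(a) { r <- as.vector(B %*% a) - q; sum(r^2) + sum(lin * a) }
  grad <- function(a) {
    as.vector(2 * crossprod(B, as.vector(B %*% a) - q)) + lin
  }

  alpha <- rep(1 / nb, nb)
  mu <- (abs(fval(alpha)) + 1) / nb
  mu_final <- gap_tol / nb
  total_newton <- 0L
  repeat {
    phi <- function(a) fval(a) - mu * sum(log(a))
    phival <- phi(alpha)
    for (it in seq_len(max_newton)) {
      g <- grad(alpha) - mu / alpha
      dinv <- alpha^2 / mu                       # inverse of barrier diagonal
      Bd <- B * rep(dinv, each = nrow(B))        # B %*% diag(dinv)
      M <- 2 * tcrossprod(Bd, B)
      diag(M) <- diag(M) + 1
      ch <- chol(M)
      solveH <- function(r) {
        t1 <- dinv * r
        t2 <- backsolve(ch, forwardsolve(t(ch), as.vector(B %*% t1)))
        t1 - 2 * dinv * as.vector(crossprod(B, t2))
      }
      h1 <- solveH(g)
      h2 <- solveH(rep(1, nb))
      nu <- -sum(h1) / sum(h2)
      step <- -h1 - nu * h2                      # Newton step in the hyperplane
      decr <- -sum(g * step)                     # Newton decrement^2
      total_newton <- total_newton + 1L
      if (decr < newton_tol * max(1, abs(phival))) break
      # fraction-to-boundary then backtracking on the barrier objective
      neg <- step < 0
      tmax <- if (any(neg)) min(1, 0.99 * min(-alpha[neg] / step[neg])) else 1
      t_ls <- tmax
      repeat {
        cand <- alpha + t_ls * step
        if (all(cand > 0)) {
          cphi <- phi(cand)
          if (cphi <= phival - 1e-4 * t_ls * decr || t_ls < 1e-12) break
        }
        t_ls <- t_ls / 2
      }
      alpha <- alpha + t_ls * step
      phival <- phi(alpha)
      if (t_ls < 1e-12) break
    }
    if (mu <= mu_final) break
    mu <- max(mu / mu_shrink, mu_final)
  }
  # snap to exact feasibility (projection is within barrier tolerance)
  alpha <- pmax(alpha, 0)
  alpha <- alpha / sum(alpha)
  list(alpha = alpha, objective = fval(alpha), iterations = total_newton,
       status = "optimal")
}

#' Accelerated projected-gradient reference solver for the same subproblem
#'
#' An independent first-order cross-check for [solve_weighted_lasso]:
#' Nesterov-accelerated projected gradient (Euclidean projection onto the
#' simplex each step, fixed 1/L step from the exact largest Hessian
#' eigenvalue, function-value restart).  Intended for small bases where it
#' can be run to convergence.
#'
#' @inheritParams solve_weighted_lasso
#' @param max_iter iteration cap.
#' @return List with `alpha` and `objective`.
#' @export
solve_weighted_lasso_pg <- function(system, lam, c_weights = NULL,
                                    max_iter = 200000L) {
  nb <- system$basis$basis_count
  if (is.null(c_weights)) c_weights <- rep(1, nb)
  st <- stack_system(system)
  B <- st$B; q <- st$q
  lin <- lam * c_weights
  G <- crossprod(B)                    # small basis only: N_B x N_B
  L <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  Bq <- as.vector(crossprod(B, q))
  fv <- function(a) sum((as.vector(B %*% a) - q)^2) + sum(lin * a)
  alpha <- rep(1 / nb, nb)
  y <- alpha
  tk <- 1
  f_prev <- fv(alpha)
  stall <- 0L
  for (it in seq_len(max_iter)) {
    g <- 2 * (as.vector(G %*% y) - Bq) + lin
    a_new <- project_simplex(y - g / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    f_new <- fv(a_new)
    if (f_new > f_prev) {             # function-value restart
      y <- alpha
      tk <- 1
      stall <- stall + 1L
      if (stall > 50L) break
      next
    }
    y <- a_new + (tk - 1) / t_new * (a_new - alpha)
    alpha <- a_new
    tk <- t_new
    if (f_prev - f_new < 1e-16 * max(1, abs(f_new))) stall <- stall + 1L
    else stall <- 0L
    f_prev <- f_new
    if (stall > 50L) break
  }
  list(alpha = alpha, objective = fv(alpha))
}

#' Euclidean projection onto the probability simplex
#'
#' @param v numeric vector.
#' @return The closest point on \{a >= 0, sum(a) = 1\}.
#' @keywords internal
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (css[rho] - 1) / rho
  pmax(v - tau, 0)
}
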