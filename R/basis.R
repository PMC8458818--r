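#' Lattice of isotropic Gaussian basis functions on [-1, 1]^4
#'
#' The joint density over (y, x1, x2, x3) is represented as a convex
#' combination of isotropic Gaussian bumps placed on a regular lattice: N
#' equally spaced points per axis (N odd, so the origin is a lattice
#' point), the full N^4 grid of centers, and M widths per center, giving
#' N_B = M * N^4 basis functions
#'   f_i(z) = (2*pi)^-2 sigma_i^-4 exp(-||z - mu_i||^2 / (2 sigma_i^2)).
#'
#' Component ordering is width-major: index i = (m - 1) * N^4 + n, where
#' width block m = 1..M follows `widths` and center n = 1..N^4 runs over
#' `expand.grid` order (axis 1 = outcome varying fastest).  The ordering is
#' arbitrary but must be stable, since coefficient vectors are stored by
#' index.
#'
#' @param n_per_axis odd integer N >= 3.
#' @param widths strictly increasing positive component sds (default: the
#'   seven production widths 0.03 ... 0.40).
#' @return An object of class `lattice_basis` with fields `n_per_axis`,
#'   `widths`, `axis_points`, `centers` (N^4 x 4 matrix), `basis_count`.
#' @examples
#' b <- build_basis(3, c(0.1, 0.2))
#' b$basis_count  # 162
#' @export
build_basis <- function(n_per_axis,
                        widths = c(0.03, 0.05, 0.10, 0.15, 0.20,
                                   0.30, 0.40)) {
  n_per_axis <- as.integer(n_per_axis)
  if (n_per_axis < 3L || n_per_axis %% 2L == 0L)
    stopf("build_basis: n_per_axis must be an odd integer >= 3, got %d",
          n_per_axis)
  if (length(widths) == 0L || any(widths <= 0))
    stopf("build_basis: widths must be positive")
  if (any(diff(widths) <= 0))
    stopf("build_basis: widths must be strictly increasing")
  ax <- seq(-1, 1, length.out = n_per_axis)
  centers <- as.matrix(expand.grid(ax, ax, ax, ax,
                                   KEEP.OUT.ATTRS = FALSE))
  dimnames(centers) <- NULL
  structure(list(n_per_axis = n_per_axis, widths = as.numeric(widths),
                 axis_points = ax, centers = centers,
                 basis_count = length(widths) * nrow(centers)),
            class = "lattice_basis")
}

#' @export
print.lattice_basis <- function(x, ...) {
  cat(sprintf("lattice_basis: N = %d per axis, M = %d widths, N_B = %d\n",
              x$n_per_axis, length(x$widths), x$basis_count))
  invisible(x)
}

# width index m and center index n for basis indices i (1-based).
basis_width_index <- function(basis, i) {
  (i - 1L) %/% nrow(basis$centers) + 1L
}
basis_center_index <- function(basis, i) {
  (i - 1L) %% nrow(basis$centers) + 1L
}

# per-component sd and center rows for a set of basis indices
basis_sigma <- function(basis, i) basis$widths[basis_width_index(basis, i)]
basis_mu <- function(basis, i) {
  basis$centers[basis_center_index(basis, i), , drop = FALSE]
}

#' Evaluate basis functions at 4D points
#'
#' @param basis a [lattice_basis].
#' @param points numeric matrix, rows = 4D evaluation points.
#' @param idx optional basis indices to evaluate (default: all).
#' @return Matrix of f_i(z), rows = points, columns = basis indices.
#' @export
eval_basis <- function(basis, points, idx = NULL) {
  stopifnot(inherits(basis, "lattice_basis"))
  points <- rbind(points)
  if (ncol(points) != 4L) stopf("eval_basis: points must have 4 columns")
  if (is.null(idx)) idx <- seq_len(basis$basis_count)
  mu <- basis_mu(basis, idx)
  sig <- basis_sigma(basis, idx)
  # squared distances points x components
  d2 <- outer(rowSums(points^2), rowSums(mu^2), "+") -
    2 * points %*% t(mu)
  d2[d2 < 0] <- 0
  peak <- 1 / ((2 * pi)^2 * sig^4)
  sweep(exp(-sweep(d2, 2, 2 * sig^2, "/")), 2, peak, "*")
}

#' Design block mapping coefficients to one axis's marginal
#'
#' Because the components are isotropic, the marginal of f_i on any axis is
#' the univariate Gaussian with mean equal to that component of its center
#' and sd sigma_i.  Entry (k, i) of the returned matrix is that Gaussian
#' density at the k-th evaluation point, so `A %*% alpha` tabulates the
#' model-implied marginal.
#'
#' @param basis a [lattice_basis].
#' @param axis axis number 1..4 (1 = outcome).
#' @param eval_points evaluation points in \[-1, 1\].
#' @return K x N_B matrix.
#' @export
marginal_design <- function(basis, axis, eval_points) {
  stopifnot(inherits(basis, "lattice_basis"), axis %in% 1:4)
  if (any(eval_points < -1 | eval_points > 1))
    stopf("marginal_design: eval_points must lie in [-1, 1]")
  ncen <- nrow(basis$centers)
  mu_ax <- basis$centers[, axis]
  out <- matrix(0, length(eval_points), basis$basis_count)
  for (m in seq_along(basis$widths)) {
    cols <- (m - 1L) * ncen + seq_len(ncen)
    out[, cols] <- stats::dnorm(outer(eval_points, mu_ax, "-"),
                                sd = basis$widths[m])
  }
  out
}

#' Moment-constraint block tying coefficients to target correlations
#'
#' For each predictor axis j, E\[x_j y\] under the mixture is
#' sum_i alpha_i mu_{x_j,i} mu_{y,i}: isotropic components carry no
#' within-component cross-covariance, so the product of center coordinates
#' is exact.  Dividing by the supplied marginal sds turns the correlation
#' identity r = (E\[x_j y\] - m_{x_j} m_y) / (s_{x_j} s_y) into one linear
#' row per predictor with right-hand side r + m_{x_j} m_y / (s_{x_j} s_y).
#'
#' @param basis a [lattice_basis].
#' @param moment_list list of 4 `moment_summary` objects (outcome first),
#'   computed from the supplied normalized marginals.
#' @param r_targets numeric length-3 vector of target correlations for
#'   predictor axes 2..4 with the outcome.
#' @return List with `A` (3 x N_B matrix) and `target` (length 3).
#' @export
moment_design <- function(basis, moment_list, r_targets) {
  stopifnot(inherits(basis, "lattice_basis"),
            length(moment_list) == 4L, length(r_targets) == 3L)
  s <- vapply(moment_list, `[[`, numeric(1), "sd")
  m <- vapply(moment_list, `[[`, numeric(1), "mean")
  if (any(s <= 0)) stopf("moment_design: zero sd in moment_list")
  ncen <- nrow(basis$centers)
  mu_y <- basis$centers[, 1]
  A <- matrix(0, 3, basis$basis_count)
  target <- numeric(3)
  for (j in 1:3) {
    ax <- j + 1L
    row_cen <- basis$centers[, ax] * mu_y / (s[ax] * s[1])
    A[j, ] <- rep(row_cen, times = length(basis$widths))
    target[j] <- r_targets[j] + m[ax] * m[1] / (s[ax] * s[1])
  }
  list(A = A, target = target)
}

#' Assemble the full constraint system for one outcome's joint fit
#'
#' Stacks the four marginal design blocks (K rows each, targets = the
#' supplied marginal densities at the evaluation points) and the 3-row
#' moment block, with per-block weights.
#'
#' @param basis a [lattice_basis].
#' @param marginals list of 4 normalized [grid_pdf]s, outcome first then
#'   the three predictors (axis order of the basis).
#' @param r_targets numeric length-3 target correlations (axes 2..4 vs the
#'   outcome).
#' @param k_points number K of equally spaced evaluation points per axis.
#' @param block_weights numeric length 5, weights w_1..w_5 on the four
#'   marginal blocks and the moment block.
#' @return An object of class `constraint_system` with fields `blocks`,
#'   `targets`, `block_weights`, `k_points`, `basis`, `moments`,
#'   `r_targets`, `eval_points`.
#' @export
constraint_system <- function(basis, marginals, r_targets,
                              k_points = 41L,
                              block_weights = c(1, 1, 1, 1, 75)) {
  stopifnot(inherits(basis, "lattice_basis"), length(marginals) == 4L,
            length(block_weights) == 5L, length(r_targets) == 3L)
  ok <- vapply(marginals, inherits, logical(1), "grid_pdf")
  if (!all(ok)) stopf("constraint_system: marginals must be grid_pdf objects")
  ev <- seq(-1, 1, length.out = k_points)
  blocks <- vector("list", 5L)
  targets <- vector("list", 5L)
  for (a in 1:4) {
    blocks[[a]] <- marginal_design(basis, a, ev)
    targets[[a]] <- stats::approx(marginals[[a]]$grid,
                                  marginals[[a]]$density, xout = ev,
                                  yleft = 0, yright = 0)$y
  }
  mom <- lapply(marginals, moments)
  md <- moment_design(basis, mom, r_targets)
  blocks[[5]] <- md$A
  targets[[5]] <- md$target
  structure(list(blocks = blocks, targets = targets,
                 block_weights = as.numeric(block_weights),
                 k_points = as.integer(k_points), basis = basis,
                 moments = mom, r_targets = r_targets, eval_points = ev),
            class = "constraint_system")
}

# Stack the weighted design and target: B = [sqrt(w_k) A_k], q = [sqrt(w_k) p_k]
stack_system <- function(system) {
  sw <- sqrt(system$block_weights)
  B <- do.call(rbind, Map(function(A, s) A * s, system$blocks, sw))
  q <- unlist(Map(function(p, s) p * s, system$targets, sw))
  list(B = B, q = q)
}

#' Objective of the weighted simplex-constrained LASSO
#'
#' sum_k w_k ||p_k - A_k alpha||^2 + lam * sum(c * alpha)  (alpha >= 0, so
#' the weighted L1 penalty is the linear form c' alpha).
#'
#' @param system a [constraint_system].
#' @param alpha coefficient vector.
#' @param lam penalty strength.
#' @param c_weights per-coefficient adaptive weights.
#' @return The objective value.
#' @export
lasso_objective <- function(system, alpha, lam, c_weights = NULL) {
  if (is.null(c_weights)) c_weights <- rep(1, length(alpha))
  fit <- 0
  for (k in 1:5) {
    r <- system$targets[[k]] - as.vector(system$blocks[[k]] %*% alpha)
    fit <- fit + system$block_weights[k] * sum(r^2)
  }
  fit + lam * sum(c_weights * alpha)
}
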