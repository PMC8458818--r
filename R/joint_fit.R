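#' Fit a sparse 4D joint density by iteratively reweighted adaptive LASSO
#'
#' The workhorse of the package.  Given normalized marginals for one
#' outcome and the three predictors plus target predictor-outcome
#' correlations, it represents the joint density p(y, x1, x2, x3) as a
#' simplex-constrained mixture over a [build_basis] lattice and selects
#' the coefficients by the iteratively reweighted scheme:
#'
#' 1. initialize the adaptive weights c = (1, ..., 1);
#' 2. solve the weighted LASSO subproblem ([solve_weighted_lasso]);
#' 3. update c_i = 1/alpha_i where alpha_i > threshold, else
#'    c_i = 1/threshold (maximal penalty keeps zeroed coefficients down);
#' 4. threshold: alpha_i <= threshold is set to 0;
#' 5. stop when the nonzero count is at most `target_nnz`, else repeat
#'    from 2 with the updated c.
#'
#' After the final thresholding the coefficients are renormalized to sum
#' to one, restoring the simplex.  If `max_outer` iterations pass without
#' reaching the sparsity target the sparsest iterate is returned with
#' `sparsity_met = FALSE` and a warning.
#'
#' @param marginals named list of 4 normalized [grid_pdf]s carrying axis
#'   transforms, in axis order: outcome first, then the three predictors
#'   (conventionally stress, sleep, exertion).
#' @param r_targets length-3 numeric vector of predictor-outcome target
#'   correlations (same predictor order), or an [effect_size_matrix] from
#'   which the column for `outcome` is taken.
#' @param outcome name of the outcome variable (used to pull `r_targets`
#'   from an effect-size matrix and to label the model).
#' @param n_per_axis lattice resolution N (odd; 9 is the reduced profile,
#'   21 the production scale).
#' @param widths component sds (default the seven production widths).
#' @param lam LASSO penalty lambda (default 1e-5).
#' @param threshold coefficient threshold t (default 1e-9).
#' @param target_nnz sparsity target N_z (default 400).
#' @param k_points marginal evaluation points K per axis (default 41).
#' @param block_weights constraint-block weights w_1..w_5 (default
#'   c(1, 1, 1, 1, 75)).
#' @param max_outer cap on reweighting iterations (default 50).
#' @param solver_control passed to [solve_weighted_lasso].
#' @param verbose print per-iteration nonzero counts.
#' @return An object of class `joint_density`; see Details for fields and
#'   the methods `print`, `summary`, `coef`, `predict`, `simulate`,
#'   `residuals`, `plot`.
#' @seealso [condition()], [recovered_stats()], [eval_slice()]
#' @export
fit_joint_density <- function(marginals, r_targets, outcome = NULL,
                              n_per_axis = 9L,
                              widths = c(0.03, 0.05, 0.10, 0.15, 0.20,
                                         0.30, 0.40),
                              lam = 1e-5, threshold = 1e-9,
                              target_nnz = 400L, k_points = 41L,
                              block_weights = c(1, 1, 1, 1, 75),
                              max_outer = 50L, solver_control = list(),
                              verbose = FALSE) {
  stopifnot(length(marginals) == 4L)
  if (is.null(outcome)) outcome <- names(marginals)[1] %||% "outcome"
  if (inherits(r_targets, "effect_size_matrix")) {
    preds <- names(marginals)[2:4]
    r_targets <- vapply(preds, function(p)
      effect_size(r_targets, p, outcome)$r, numeric(1))
  }
  system <- constraint_system(build_basis(n_per_axis, widths), marginals,
                              r_targets, k_points, block_weights)
  model <- adaptive_sparsify(system, lam = lam, threshold = threshold,
                             target_nnz = target_nnz, max_outer = max_outer,
                             solver_control = solver_control,
                             verbose = verbose)
  model$variables <- names(marginals) %||%
    c(outcome, "stress", "sleep", "exertion")
  model$outcome <- outcome
  model$transforms <- lapply(marginals, `[[`, "transform")
  model$supplied <- marginals
  model
}

#' Iteratively reweighted sparsification over a prebuilt constraint system
#'
#' The inner engine of [fit_joint_density]; exposed separately so
#' construct-and-recover experiments can run on systems built directly
#' from a known sparse coefficient vector.
#'
#' @param system a [constraint_system].
#' @inheritParams fit_joint_density
#' @return A `joint_density` (without variable names/transforms, which
#'   [fit_joint_density] attaches).
#' @export
adaptive_sparsify <- function(system, lam = 1e-5, threshold = 1e-9,
                              target_nnz = 400L, max_outer = 50L,
                              solver_control = list(), verbose = FALSE) {
  stopifnot(inherits(system, "constraint_system"),
            threshold > 0, target_nnz >= 1L)
  nb <- system$basis$basis_count
  stacked <- stack_system(system)
  c_weights <- rep(1, nb)
  best <- NULL
  nnz_path <- integer(0)
  sparsity_met <- FALSE
  for (iter in seq_len(max_outer)) {
    sol <- solve_weighted_lasso(system, lam = lam, c_weights = c_weights,
                                control = solver_control, stacked = stacked)
    a <- sol$alpha
    c_weights <- ifelse(a > threshold, 1 / a, 1 / threshold)
    a[a <= threshold] <- 0
    nnz <- sum(a > 0)
    nnz_path <- c(nnz_path, nnz)
    if (verbose)
      message(sprintf("  reweight iter %d: nnz = %d, objective = %.6g",
                      iter, nnz, sol$objective))
    if (is.null(best) || nnz < best$nnz)
      best <- list(alpha = a, nnz = nnz, objective = sol$objective)
    if (nnz <= target_nnz) { sparsity_met <- TRUE; break }
  }
  if (!sparsity_met)
    warning(sprintf(paste0("adaptive_sparsify: sparsity target %d not ",
                           "reached in %d iterations (best nnz = %d); ",
                           "returning sparsest iterate"),
                    target_nnz, max_outer, best$nnz))
  a <- best$alpha / sum(best$alpha)          # restore the simplex
  idx <- which(a > 0)
  structure(list(basis = system$basis,
                 alpha_idx = idx, alpha_val = a[idx],
                 nnz = length(idx),
                 config = list(lam = lam, threshold = threshold,
                               target_nnz = target_nnz,
                               k_points = system$k_points,
                               block_weights = system$block_weights,
                               max_outer = max_outer),
                 r_targets = system$r_targets,
                 moments_supplied = system$moments,
                 diagnostics = list(nnz_path = nnz_path,
                                    objective = best$objective,
                                    sparsity_met = sparsity_met),
                 variables = NULL, outcome = NULL,
                 transforms = NULL, supplied = NULL),
            class = "joint_density")
}

# dense coefficient vector of a joint_density
joint_alpha <- function(model) {
  a <- numeric(model$basis$basis_count)
  a[model$alpha_idx] <- model$alpha_val
  a
}

# per-component centers (nnz x 4) and sds (nnz) of the retained components
joint_components <- function(model) {
  list(mu = basis_mu(model$basis, model$alpha_idx),
       sigma = basis_sigma(model$basis, model$alpha_idx),
       weight = model$alpha_val)
}

#' Model-implied ("recovered") marginals, moments and correlations
#'
#' The fidelity report comparing what the fitted joint density implies
#' with what was supplied: recovered marginals on each axis (the
#' alpha-weighted sums of univariate component Gaussians), recovered
#' pairwise predictor-outcome correlations from the model's own moments,
#' and L1 / max discrepancies against the supplied inputs when the model
#' carries them.
#'
#' @param model a `joint_density`.
#' @param n_grid grid resolution for the recovered marginals.
#' @return An object of class `joint_fidelity`: list with
#'   `marginals` (list of 4 [grid_pdf]), `r_recovered`, `r_supplied`,
#'   `r_abs_error`, `marginal_l1` (length 4, `NA` without supplied
#'   marginals), `moments` (model-implied per-axis mean/sd).
#' @export
recovered_stats <- function(model, n_grid = 512L) {
  stopifnot(inherits(model, "joint_density"))
  comp <- joint_components(model)
  marg <- vector("list", 4L)
  l1 <- rep(NA_real_, 4L)
  for (ax in 1:4) {
    # components are exact Gaussian densities, so the implied marginal
    # integrates to 1 over the real line; tabulate on a grid wide enough
    # to hold every component's tails
    lo <- min(-1, comp$mu[, ax] - 6 * comp$sigma)
    hi <- max(1, comp$mu[, ax] + 6 * comp$sigma)
    g <- seq(lo, hi, length.out = n_grid)
    d <- recovered_marginal_eval(comp, ax, g)
    marg[[ax]] <- grid_pdf(g, d, transform = model$transforms[[ax]],
                           tol = 1e-4)
    if (!is.null(model$supplied)) {
      sup <- stats::approx(model$supplied[[ax]]$grid,
                           model$supplied[[ax]]$density, xout = g,
                           yleft = 0, yright = 0)$y
      l1[ax] <- trapz(g, abs(d - sup))
    }
  }
  # model moments: E[z_a] = sum alpha mu_a ; E[z_a^2] = sum alpha (mu^2+sig^2)
  w <- comp$weight
  m <- colSums(w * comp$mu)
  v <- colSums(w * (comp$mu^2 + comp$sigma^2)) - m^2
  s <- sqrt(v)
  r_rec <- vapply(1:3, function(j) {
    exy <- sum(w * comp$mu[, j + 1] * comp$mu[, 1])
    (exy - m[j + 1] * m[1]) / (s[j + 1] * s[1])
  }, numeric(1))
  names(r_rec) <- if (!is.null(model$variables)) model$variables[2:4]
  out <- list(marginals = marg, r_recovered = r_rec,
              r_supplied = model$r_targets,
              r_abs_error = abs(r_rec - model$r_targets),
              marginal_l1 = l1,
              moments = list(mean = m, sd = s),
              variables = model$variables)
  class(out) <- "joint_fidelity"
  out
}

recovered_marginal_eval <- function(comp, axis, grid) {
  d <- numeric(length(grid))
  for (i in seq_along(comp$weight))
    d <- d + comp$weight[i] *
      stats::dnorm(grid, comp$mu[i, axis], comp$sigma[i])
  d
}

#' @export
print.joint_fidelity <- function(x, ...) {
  cat("Supplied vs recovered effect sizes (r):\n")
  df <- data.frame(supplied = x$r_supplied, recovered = round(x$r_recovered, 4),
                   abs_error = round(x$r_abs_error, 4))
  rownames(df) <- names(x$r_recovered) %||% paste0("x", 1:3)
  print(df)
  if (!all(is.na(x$marginal_l1))) {
    cat("\nMarginal L1 discrepancies (supplied vs recovered):\n")
    l1 <- round(x$marginal_l1, 4)
    names(l1) <- x$variables %||% paste0("axis", 1:4)
    print(l1)
  }
  invisible(x)
}

#' Density values of a joint model on a lower-dimensional slice
#'
#' Fixes some axes at given values and tabulates the joint density on a
#' tensor grid over the remaining axes (for export and external 2D/3D
#' plotting).
#'
#' @param model a `joint_density`.
#' @param fixed named or integer-indexed numeric vector of fixed axis
#'   values in \[-1, 1\]; names may be axis numbers ("1".."4") or variable
#'   names.
#' @param free_grids list of numeric grids, one per free axis, in the
#'   model's axis order.
#' @return An array of density values with `dim = lengths(free_grids)`,
#'   with attributes `free_axes` and `grids`.
#' @export
eval_slice <- function(model, fixed, free_grids = NULL) {
  stopifnot(inherits(model, "joint_density"))
  fx_axes <- resolve_axes(model, names(fixed) %||% stop("fixed must be named"))
  if (any(fixed < -1 | fixed > 1))
    stopf("eval_slice: fixed values must lie in [-1, 1]")
  free_axes <- setdiff(1:4, fx_axes)
  if (length(free_axes) == 0L) stopf("eval_slice: no free axes")
  if (is.null(free_grids))
    free_grids <- rep(list(seq(-1, 1, length.out = 61L)), length(free_axes))
  stopifnot(length(free_grids) == length(free_axes))
  comp <- joint_components(model)
  nnz <- length(comp$weight)
  # weight of each component on the fixed axes
  wfix <- comp$weight
  for (k in seq_along(fx_axes))
    wfix <- wfix * stats::dnorm(fixed[k], comp$mu[, fx_axes[k]], comp$sigma)
  # per-free-axis univariate factors, then accumulate the tensor product
  out <- array(0, dim = vapply(free_grids, length, integer(1)))
  for (i in seq_len(nnz)) {
    if (wfix[i] == 0) next
    factors <- lapply(seq_along(free_axes), function(k)
      stats::dnorm(free_grids[[k]], comp$mu[i, free_axes[k]], comp$sigma[i]))
    out <- out + wfix[i] * Reduce(`%o%`, factors)
  }
  attr(out, "free_axes") <- free_axes
  attr(out, "grids") <- free_grids
  out
}

resolve_axes <- function(model, keys) {
  vapply(keys, function(k) {
    if (!is.na(suppressWarnings(as.integer(k)))) return(as.integer(k))
    i <- match(k, model$variables)
    if (is.na(i)) stopf("unknown axis '%s'", k)
    i
  }, integer(1))
}

#' @export
print.joint_density <- function(x, ...) {
  cat(sprintf("joint_density%s: N = %d per axis, M = %d widths, N_B = %d\n",
              if (!is.null(x$outcome)) paste0(" [", x$outcome, "]") else "",
              x$basis$n_per_axis, length(x$basis$widths),
              x$basis$basis_count))
  cat(sprintf("  %d nonzero coefficients (target <= %d%s), sum = %.6f\n",
              x$nnz, x$config$target_nnz,
              if (isTRUE(x$diagnostics$sparsity_met)) "" else ", NOT met",
              sum(x$alpha_val)))
  invisible(x)
}

#' @export
summary.joint_density <- function(object, ...) {
  fid <- recovered_stats(object)
  cat(sprintf("Joint density for outcome '%s'\n",
              object$outcome %||% "(unnamed)"))
  print(object)
  cat(sprintf("  reweighting iterations: %d (nnz path: %s)\n",
              length(object$diagnostics$nnz_path),
              paste(object$diagnostics$nnz_path, collapse = " -> ")))
  print(fid)
  invisible(fid)
}

#' @export
coef.joint_density <- function(object, sparse = TRUE, ...) {
  if (sparse) {
    stats::setNames(object$alpha_val, object$alpha_idx)
  } else joint_alpha(object)
}

#' @export
residuals.joint_density <- function(object, ...) {
  if (is.null(object$supplied))
    stopf("residuals: model carries no supplied marginals")
  system <- constraint_system(object$basis, object$supplied,
                              object$r_targets, object$config$k_points,
                              object$config$block_weights)
  a <- joint_alpha(object)
  lapply(stats::setNames(1:5, c(object$variables, "moment")), function(k)
    system$targets[[k]] - as.vector(system$blocks[[k]] %*% a))
}

#' @export
plot.joint_density <- function(x, axes = 1:4, ...) {
  if (is.null(x$supplied))
    stopf("plot: model carries no supplied marginals")
  fid <- recovered_stats(x)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ax in axes) {
    sup <- x$supplied[[ax]]
    plot(sup$grid, sup$density, type = "l",
         xlab = x$variables[ax] %||% paste0("axis", ax), ylab = "density",
         main = sprintf("L1 = %.3f", fid$marginal_l1[ax]), ...)
    graphics::lines(fid$marginals[[ax]]$grid, fid$marginals[[ax]]$density,
                    lty = 2, col = 2)
  }
  invisible(x)
}

#' Serialize / restore a fitted joint density
#'
#' One text file: a `#`-prefixed JSON header (basis geometry, config,
#' axis transforms, variable names) followed by the sparse coefficient
#' table CSV `basis_index,width_index,center_index,alpha`.
#'
#' @param model a `joint_density`.
#' @param path file path.
#' @return `write_joint_density` returns `path` invisibly;
#'   `read_joint_density` returns the model (without supplied marginals,
#'   which are stored separately as grid_pdf files).
#' @export
write_joint_density <- function(model, path) {
  stopifnot(inherits(model, "joint_density"))
  meta <- list(format = "perfdens.joint_density", version = 1L,
               n_per_axis = model$basis$n_per_axis,
               widths = model$basis$widths,
               config = model$config,
               r_targets = model$r_targets,
               variables = model$variables,
               outcome = model$outcome,
               sparsity_met = isTRUE(model$diagnostics$sparsity_met),
               transforms = lapply(model$transforms, function(tr)
                 if (is.null(tr)) NULL
                 else list(physical_lo = tr$physical_lo,
                           physical_hi = tr$physical_hi)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA, null = "null")), con)
  utils::write.csv(data.frame(
    basis_index = model$alpha_idx,
    width_index = basis_width_index(model$basis, model$alpha_idx),
    center_index = basis_center_index(model$basis, model$alpha_idx),
    alpha = model$alpha_val), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_joint_density
#' @export
read_joint_density <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# "))
    stopf("read_joint_density: missing JSON header in %s", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]),
                             simplifyVector = FALSE)
  df <- utils::read.csv(text = lines[-1])
  basis <- build_basis(meta$n_per_axis, unlist(meta$widths))
  transforms <- lapply(meta$transforms, function(tr)
    if (is.null(tr)) NULL
    else axis_transform(tr$physical_lo, tr$physical_hi))
  config <- lapply(meta$config, function(v)
    if (is.list(v)) unlist(v) else v)
  structure(list(basis = basis, alpha_idx = as.integer(df$basis_index),
                 alpha_val = df$alpha, nnz = nrow(df),
                 config = config, r_targets = unlist(meta$r_targets),
                 moments_supplied = NULL,
                 diagnostics = list(sparsity_met =
                                      isTRUE(meta$sparsity_met)),
                 variables = as.character(unlist(meta$variables)),
                 outcome = meta$outcome,
                 transforms = transforms, supplied = NULL),
            class = "joint_density")
}
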