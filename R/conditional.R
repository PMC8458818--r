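#' Conditional outcome density given the three predictor values
#'
#' For a mixture of isotropic Gaussians the conditional density of the
#' outcome given the predictors is available in closed form: each retained
#' component's weight is reweighted by its 3D Gaussian density at the
#' conditioning point x, and the outcome components are the univariate
#' Gaussians (mu_{y,i}, sigma_i).  The result is tabulated on an outcome
#' grid wide enough to hold the full mixture mass.
#'
#' @param model a `joint_density`.
#' @param x length-3 predictor values (axis order of the model:
#'   conventionally stress, sleep, exertion).
#' @param units "normalized" (x already in \[-1, 1\]) or "physical"
#'   (converted through the stored axis transforms; values outside the
#'   modeled range are clamped to \[-1, 1\] with a warning).
#' @param n_grid outcome grid resolution.
#' @return A list of class `conditional_density`: `pdf` (a [grid_pdf] on
#'   the normalized outcome axis, carrying the outcome transform),
#'   `weights` (conditional component weights, summing to 1), `x` (the
#'   normalized conditioning point).
#' @export
condition <- function(model, x, units = c("normalized", "physical"),
                      n_grid = 512L) {
  stopifnot(inherits(model, "joint_density"), length(x) == 3L)
  units <- match.arg(units)
  if (units == "physical") {
    x <- vapply(1:3, function(j) {
      tr <- model$transforms[[j + 1]]
      if (is.null(tr))
        stopf("condition: no axis transform stored for predictor %d", j)
      to_normalized(tr, x[j])
    }, numeric(1))
  }
  if (any(x < -1 | x > 1)) {
    warning("condition: predictor point outside [-1, 1]; clamping")
    x <- pmin(pmax(x, -1), 1)
  }
  comp <- joint_components(model)
  # log-domain reweighting for numerical safety at remote x
  lw <- log(comp$weight)
  for (j in 1:3)
    lw <- lw + stats::dnorm(x[j], comp$mu[, j + 1], comp$sigma, log = TRUE)
  mx <- max(lw)
  if (!is.finite(mx) || exp(mx) < 1e-300)
    stopf("condition: conditioning point outside model support")
  w <- exp(lw - mx)
  w <- w / sum(w)
  lo <- min(comp$mu[, 1] - 6 * comp$sigma)
  hi <- max(comp$mu[, 1] + 6 * comp$sigma)
  g <- seq(lo, hi, length.out = n_grid)
  d <- numeric(n_grid)
  for (i in seq_along(w))
    if (w[i] > 0)
      d <- d + w[i] * stats::dnorm(g, comp$mu[i, 1], comp$sigma[i])
  structure(list(pdf = grid_pdf(g, d / trapz(g, d),
                                transform = model$transforms[[1]]),
                 weights = w, x = x),
            class = "conditional_density")
}

#' @export
print.conditional_density <- function(x, ...) {
  cat(sprintf("conditional_density at x = (%s): %d active components\n",
              paste(signif(x$x, 3), collapse = ", "),
              sum(x$weights > 1e-12)))
  print(x$pdf)
  invisible(x)
}

#' Summary statistics of a conditional outcome density, in physical units
#'
#' Moments by trapezoidal quadrature, mode by grid argmax refined with
#' local quadratic interpolation, median and percentiles by inverse CDF,
#' and a central interval at the requested level.  All values are mapped
#' to physical units through the density's axis transform when present.
#'
#' @param cond a `conditional_density` (or bare [grid_pdf]).
#' @param levels percentile levels to report (the central interval uses
#'   `interval_level`).
#' @param interval_level central interval mass, default 0.95.
#' @return An object of class `conditional_summary` with fields `mean`,
#'   `sd`, `mode`, `median`, `percentiles`, `skew`, `excess_kurtosis`,
#'   `interval` (lo/hi), `interval_level`.
#' @export
summarize_conditional <- function(cond,
                                  levels = c(0.025, 0.25, 0.5, 0.75, 0.975),
                                  interval_level = 0.95) {
  pdf <- if (inherits(cond, "conditional_density")) cond$pdf else cond
  stopifnot(inherits(pdf, "grid_pdf"))
  phys <- if (is.null(pdf$transform)) pdf else denormalize_axis(pdf)
  g <- phys$grid; d <- phys$density
  m <- trapz(g, g * d)
  v <- trapz(g, (g - m)^2 * d)
  s <- sqrt(v)
  skew <- trapz(g, (g - m)^3 * d) / s^3
  exkurt <- trapz(g, (g - m)^4 * d) / s^4 - 3
  # mode: argmax + quadratic refinement through the three nearest points;
  # on ties the smallest-value mode is reported
  pk <- which(d == max(d))
  if (length(pk) > 1L) {
    message("summarize_conditional: multimodal tie; reporting smallest mode")
    pk <- pk[1]
  }
  mode <- if (pk > 1L && pk < length(g)) {
    y0 <- d[pk - 1]; y1 <- d[pk]; y2 <- d[pk + 1]
    den <- y0 - 2 * y1 + y2
    off <- if (den < 0) 0.5 * (y0 - y2) / den else 0
    g[pk] + off * (g[pk + 1] - g[pk])
  } else g[pk]
  lv <- sort(unique(c(levels, 0.5,
                      (1 - interval_level) / 2, 1 - (1 - interval_level) / 2)))
  qs <- grid_pdf_quantile(phys, lv)
  names(qs) <- sprintf("%g", lv)
  alpha2 <- (1 - interval_level) / 2
  structure(list(mean = m, sd = s, mode = mode,
                 median = qs[["0.5"]],
                 percentiles = qs[sprintf("%g", sort(unique(levels)))],
                 skew = skew, excess_kurtosis = exkurt,
                 interval = c(lo = qs[[sprintf("%g", alpha2)]],
                              hi = qs[[sprintf("%g", 1 - alpha2)]]),
                 interval_level = interval_level),
            class = "conditional_summary")
}

#' @export
print.conditional_summary <- function(x, ...) {
  cat(sprintf("mean %.4g  sd %.4g  mode %.4g  median %.4g\n",
              x$mean, x$sd, x$mode, x$median))
  cat(sprintf("skew %.3f  excess kurtosis %.3f  %d%% interval [%.4g, %.4g]\n",
              x$skew, x$excess_kurtosis, round(100 * x$interval_level),
              x$interval[["lo"]], x$interval[["hi"]]))
  invisible(x)
}

#' Predict conditional outcome summaries from a fitted joint density
#'
#' The `predict` method conditions the joint density on each row of
#' `newdata` and summarizes the resulting outcome density.
#'
#' @param object a `joint_density`.
#' @param newdata numeric length-3 vector or a 3-column matrix/data.frame
#'   of predictor values.
#' @param units "normalized" or "physical" (see [condition]).
#' @param summarize if `FALSE`, return the `conditional_density` objects
#'   themselves.
#' @param ... passed to [summarize_conditional].
#' @return A data.frame of summaries (one row per conditioning point), or
#'   a list of `conditional_density` when `summarize = FALSE`.
#' @export
predict.joint_density <- function(object, newdata,
                                  units = c("normalized", "physical"),
                                  summarize = TRUE, ...) {
  units <- match.arg(units)
  xm <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1)
        else as.matrix(newdata)
  if (ncol(xm) != 3L) stopf("predict: newdata must have 3 predictor columns")
  conds <- lapply(seq_len(nrow(xm)), function(i)
    condition(object, xm[i, ], units = units))
  if (!summarize) return(conds)
  do.call(rbind, lapply(conds, function(cd) {
    s <- summarize_conditional(cd, ...)
    data.frame(mean = s$mean, sd = s$sd, mode = s$mode, median = s$median,
               lo = s$interval[["lo"]], hi = s$interval[["hi"]],
               skew = s$skew, excess_kurtosis = s$excess_kurtosis)
  }))
}

#' Conditional summaries for all three outcomes at one predictor point
#'
#' Conditions each outcome's joint density on the same predictor values
#' and returns one summary per outcome.  All models must share identical
#' predictor axis transforms (they were built from the same predictor
#' marginals).
#'
#' @param models named list of three `joint_density` objects (one per
#'   outcome).
#' @param x length-3 predictor values.
#' @param units "normalized" or "physical".
#' @param ... passed to [summarize_conditional].
#' @return A data.frame with one row per outcome.
#' @export
batch_predict <- function(models, x, units = c("normalized", "physical"),
                          ...) {
  stopifnot(is.list(models), length(models) == 3L)
  units <- match.arg(units)
  ref <- models[[1]]$transforms[2:4]
  for (m in models[-1]) {
    for (j in 1:3) {
      a <- ref[[j]]; b <- m$transforms[[j + 1]]
      same <- (is.null(a) && is.null(b)) ||
        (!is.null(a) && !is.null(b) &&
           isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12)))
      if (!same)
        stopf("batch_predict: models disagree on predictor %d transform", j)
    }
  }
  out <- do.call(rbind, lapply(models, function(m) {
    s <- summarize_conditional(condition(m, x, units = units), ...)
    data.frame(outcome = m$outcome %||% NA_character_,
               mean = s$mean, sd = s$sd, mode = s$mode, median = s$median,
               lo = s$interval[["lo"]], hi = s$interval[["hi"]],
               skew = s$skew, excess_kurtosis = s$excess_kurtosis)
  }))
  rownames(out) <- NULL
  out
}
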