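#' Latent Gaussian mixture over the fused stress scale
#'
#' @param weights mixture weights in \[0, 1\] summing to 1 (within 1e-9).
#' @param means component means (any reals).
#' @param sds component standard deviations, all > 0.
#' @return An object of class `latent_mixture`.
#' @export
latent_mixture <- function(weights, means, sds) {
  stopifnot(length(weights) == length(means),
            length(means) == length(sds))
  if (any(weights < -1e-12 | weights > 1 + 1e-12))
    stopf("latent_mixture: weights must lie in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-9)
    stopf("latent_mixture: weights sum to %.12g, not 1", sum(weights))
  if (any(sds <= 0)) stopf("latent_mixture: sds must be positive")
  structure(list(weights = pmin(pmax(weights, 0), 1),
                 means = as.numeric(means), sds = as.numeric(sds)),
            class = "latent_mixture")
}

# Mixture density evaluated at s (vectorized).
mixture_density <- function(mixture, s) {
  out <- numeric(length(s))
  for (c in seq_along(mixture$weights))
    out <- out + mixture$weights[c] *
      stats::dnorm(s, mixture$means[c], mixture$sds[c])
  out
}

#' Affine measurement model for one stress source
#'
#' A source's raw datum d is modeled as d = a * s + b with s the latent
#' stress value; the initialization a = sample sd, b = sample mean makes
#' (d - b) / a a generalized z-score.
#'
#' @param a nonzero scale.
#' @param b offset.
#' @return An object of class `affine_source_model`.
#' @export
affine_source_model <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!is.finite(a) || a == 0) stopf("affine_source_model: a must be nonzero")
  structure(list(a = a, b = b), class = "affine_source_model")
}

#' Density of one source's datum under the latent-scale model
#'
#' Change of variables through d = a s + b gives
#' p(d | theta) = (1/|a|) p_S((d - b)/a).
#'
#' @param d numeric data values.
#' @param theta an [affine_source_model].
#' @param mixture a [latent_mixture].
#' @return Nonnegative densities, one per element of `d`.
#' @export
source_density <- function(d, theta, mixture) {
  stopifnot(inherits(theta, "affine_source_model"),
            inherits(mixture, "latent_mixture"))
  mixture_density(mixture, (d - theta$b) / theta$a) / abs(theta$a)
}

#' Initial fusion model: per-source z-score maps and a flat wide mixture
#'
#' Each source's affine parameters are initialized to its sample standard
#' deviation (scale a) and sample mean (offset b).  The shared latent
#' mixture starts as `n_components` Gaussians of identical weight and
#' width 1/N_c, with means linearly spaced over \[-2, 4\]:
#' mu_c = -2 + 6 (c - 1) / (N_c - 1).
#'
#' @param sources list of [source_series] (same variable; units may
#'   differ, which is the point of the fusion).
#' @param n_components number of mixture components N_c >= 2 (default 6).
#' @return A `fusion_model` (see [fit_latent_fusion]).
#' @export
init_fusion <- function(sources, n_components = 6L) {
  if (!is.list(sources) || length(sources) == 0L)
    stopf("init_fusion: need at least one source")
  ok <- vapply(sources, inherits, logical(1), "source_series")
  if (!all(ok)) stopf("init_fusion: sources must be source_series objects")
  n_components <- as.integer(n_components)
  if (n_components < 2L) stopf("init_fusion: n_components must be >= 2")
  source_models <- lapply(sources, function(s) {
    if (s$n < 2L) stopf("init_fusion: source '%s' has fewer than 2 values",
                        s$source_id)
    a <- stats::sd(s$values)
    if (a == 0) stopf("init_fusion: source '%s' has zero variance",
                      s$source_id)
    affine_source_model(a = a, b = mean(s$values))
  })
  names(source_models) <- vapply(sources, `[[`, character(1), "source_id")
  cc <- seq_len(n_components)
  mixture <- latent_mixture(weights = rep(1 / n_components, n_components),
                            means = -2 + 6 * (cc - 1) / (n_components - 1),
                            sds = rep(1 / n_components, n_components))
  new_fusion_model(source_models, mixture, fitted = FALSE)
}

new_fusion_model <- function(source_models, mixture, fitted,
                             nll = NA_real_, convergence = NA_integer_) {
  structure(list(source_models = source_models, mixture = mixture,
                 anchor = 1L, fitted = fitted, nll = nll,
                 convergence = convergence),
            class = "fusion_model")
}

#' Negative log-likelihood of multi-source data under a fusion model
#'
#' Sums -ln p(d | theta_i) over every datum of every source, treating all
#' observations as independent draws from their source-conditional
#' densities.  Computed with log-sum-exp over mixture components, so it
#' stays finite unless a datum has exactly zero density under every
#' component.
#'
#' @param model a `fusion_model`.
#' @param sources list of [source_series] aligned with
#'   `model$source_models`.
#' @return A single number (+Inf only on exact underflow of a datum).
#' @export
negative_log_likelihood <- function(model, sources) {
  stopifnot(inherits(model, "fusion_model"))
  if (length(sources) != length(model$source_models))
    stopf("negative_log_likelihood: %d sources but %d source models",
          length(sources), length(model$source_models))
  mix <- model$mixture
  lw <- log(mix$weights)
  keep <- is.finite(lw)   # zero-weight components contribute nothing
  total <- 0
  for (i in seq_along(sources)) {
    th <- model$source_models[[i]]
    s <- (sources[[i]]$values - th$b) / th$a
    lmat <- outer(s, mix$means[keep], function(x, m) x - m)
    lmat <- stats::dnorm(sweep(lmat, 2, mix$sds[keep], "/"), log = TRUE)
    lmat <- sweep(lmat, 2, lw[keep] - log(mix$sds[keep]), "+")
    total <- total - sum(log_sum_exp_rows(lmat) - log(abs(th$a)))
  }
  total
}

# pack/unpack the free parameters for the optimizer:
# sources 2..N: log(a_i), b_i  (source 1 frozen = anchor)
# mixture: eta_2..N_c (softmax logits, eta_1 = 0), means, log(sd - floor)
fusion_pack <- function(model, sd_floor) {
  sm <- model$source_models
  free <- unlist(lapply(sm[-1], function(t) c(log(abs(t$a)), t$b)))
  mix <- model$mixture
  eta <- log(pmax(mix$weights, 1e-12))
  c(free, eta[-1] - eta[1], mix$means,
    log(pmax(mix$sds - sd_floor, 1e-12)))
}

fusion_unpack <- function(par, template, sd_floor) {
  sm <- template$source_models
  n_src <- length(sm)
  nc <- length(template$mixture$weights)
  i <- 0L
  if (n_src > 1L) {
    for (k in 2:n_src) {
      sm[[k]] <- affine_source_model(a = max(exp(par[i + 1L]), 1e-12),
                                     b = par[i + 2L])
      i <- i + 2L
    }
  }
  eta <- c(0, par[i + seq_len(nc - 1L)]); i <- i + nc - 1L
  w <- exp(eta - max(eta)); w <- w / sum(w)
  means <- par[i + seq_len(nc)]; i <- i + nc
  sds <- sd_floor + exp(par[i + seq_len(nc)])
  new_fusion_model(sm, latent_mixture(w, means, sds), fitted = TRUE)
}

#' Fit the latent-scale fusion model by joint maximum likelihood
#'
#' Jointly optimizes every source's affine parameters and the shared
#' latent mixture by minimizing [negative_log_likelihood], starting from
#' [init_fusion] (or a supplied init).  The latent scale is anchored by
#' freezing the first source's affine parameters at their initialization,
#' which removes the affine indeterminacy of the latent axis; component
#' weights are optimized on the simplex through a softmax parameterization
#' and standard deviations through a log map with floor `sd_floor`.  The
#' optimization is a single deterministic quasi-Newton run, so repeated
#' fits of the same data give identical parameters.
#'
#' @param sources list of [source_series], one per measurement instrument.
#' @param n_components latent mixture size N_c (default 6).
#' @param init optional starting `fusion_model` (default [init_fusion]).
#' @param sd_floor smallest admissible component sd (default 1e-3),
#'   preventing collapse onto single data points.
#' @param maxit optimizer iteration cap.
#' @return A `fusion_model` with `fitted = TRUE`, the achieved `nll`, and
#'   the optimizer convergence code.  If the optimizer fails to improve on
#'   the initialization the initialization is returned with a warning.
#' @export
fit_latent_fusion <- function(sources, n_components = 6L, init = NULL,
                              sd_floor = 1e-3, maxit = 1000L) {
  if (is.null(init)) init <- init_fusion(sources, n_components)
  stopifnot(inherits(init, "fusion_model"))
  nll0 <- negative_log_likelihood(init, sources)
  obj <- function(par) {
    v <- tryCatch({
      m <- fusion_unpack(par, init, sd_floor)
      negative_log_likelihood(m, sources)
    }, error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(fusion_pack(init, sd_floor), obj, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  fit <- fusion_unpack(opt$par, init, sd_floor)
  fit$nll <- opt$value
  fit$convergence <- opt$convergence
  if (opt$value > nll0) {
    warning("fit_latent_fusion: optimizer failed to improve on the ",
            "initialization; returning the initial model")
    init$fitted <- TRUE
    init$nll <- nll0
    init$convergence <- 1L
    return(init)
  }
  fit
}

#' Latent stress marginal implied by a fusion model
#'
#' Tabulates the fitted latent mixture density p_S(s) on a grid.  This is
#' the stress marginal the joint-density construction consumes.
#'
#' @param model a `fusion_model`.
#' @param lo,hi grid bounds; defaults cover every component's mean +/- 6 sd.
#' @param n_grid number of grid points.
#' @return A [grid_pdf] on the latent (anchored) scale.
#' @export
fused_marginal <- function(model, lo = NULL, hi = NULL, n_grid = 512L) {
  stopifnot(inherits(model, "fusion_model"))
  mix <- model$mixture
  if (is.null(lo)) lo <- min(mix$means - 6 * mix$sds)
  if (is.null(hi)) hi <- max(mix$means + 6 * mix$sds)
  g <- seq(lo, hi, length.out = n_grid)
  d <- mixture_density(mix, g)
  grid_pdf(g, d / trapz(g, d))
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("fusion_model: %d sources, %d latent components%s\n",
              length(x$source_models), length(x$mixture$weights),
              if (isTRUE(x$fitted)) sprintf(" (fitted, nll = %.4f)", x$nll)
              else " (initialization)"))
  invisible(x)
}

#' @export
summary.fusion_model <- function(object, ...) {
  sm <- do.call(rbind, lapply(object$source_models, function(t)
    data.frame(a = t$a, b = t$b)))
  sm$anchored <- seq_len(nrow(sm)) == object$anchor
  mix <- with(object$mixture,
              data.frame(weight = weights, mean = means, sd = sds))
  out <- list(sources = sm, mixture = mix, nll = object$nll,
              fitted = object$fitted)
  class(out) <- "summary.fusion_model"
  out
}

#' @export
print.summary.fusion_model <- function(x, ...) {
  cat("Per-source affine models (d = a*s + b):\n")
  print(x$sources)
  cat("\nLatent mixture:\n")
  print(x$mixture, row.names = FALSE)
  if (x$fitted && is.finite(x$nll))
    cat(sprintf("\nNegative log-likelihood: %.4f\n", x$nll))
  invisible(x)
}

#' @export
coef.fusion_model <- function(object, ...) {
  sm <- object$source_models
  c(stats::setNames(unlist(lapply(sm, function(t) c(t$a, t$b))),
                    paste0(rep(names(sm) %||% seq_along(sm), each = 2),
                           c(".a", ".b"))),
    stats::setNames(object$mixture$weights,
                    paste0("weight", seq_along(object$mixture$weights))),
    stats::setNames(object$mixture$means,
                    paste0("mean", seq_along(object$mixture$means))),
    stats::setNames(object$mixture$sds,
                    paste0("sd", seq_along(object$mixture$sds))))
}

#' @export
logLik.fusion_model <- function(object, ...) {
  if (!is.finite(object$nll))
    stopf("logLik: model has no stored likelihood (unfitted?)")
  val <- -object$nll
  attr(val, "df") <- 2 * (length(object$source_models) - 1L) +
    3 * length(object$mixture$weights) - 1L
  class(val) <- "logLik"
  val
}

#' Serialize / restore a fusion model as flat JSON
#'
#' @param model a `fusion_model`.
#' @param path output file path.
#' @return `write_fusion_model` returns `path` invisibly;
#'   `read_fusion_model` returns the `fusion_model`.
#' @export
write_fusion_model <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  obj <- list(format = "perfdens.fusion_model", version = 1L,
              anchor = model$anchor,
              sources = lapply(model$source_models,
                               function(t) list(a = t$a, b = t$b)),
              weights = model$mixture$weights,
              means = model$mixture$means,
              sds = model$mixture$sds,
              fitted = isTRUE(model$fitted), nll = model$nll)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fusion_model
#' @export
read_fusion_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sm <- lapply(obj$sources, function(t) affine_source_model(t$a, t$b))
  m <- new_fusion_model(sm, latent_mixture(obj$weights, obj$means, obj$sds),
                        fitted = isTRUE(obj$fitted),
                        nll = obj$nll %||% NA_real_)
  m$anchor <- obj$anchor
  m
}
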