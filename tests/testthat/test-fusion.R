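make_sources <- function(seed = 2, n = c(80, 120)) {
  withr::with_seed(seed, list(
    source_series("s1", "stress", "u1", rnorm(n[1], 10, 2)),
    source_series("s2", "stress", "u2", rexp(n[2], 0.2))))
}

test_that("initialization places flat equal-width components over [-2, 4]", {
  src <- make_sources()
  init <- init_fusion(src, n_components = 6)
  expect_equal(init$mixture$means, seq(-2, 4, length.out = 6))
  expect_equal(init$mixture$means[1], -2)
  expect_equal(init$mixture$means[6], 4)
  expect_equal(init$mixture$weights, rep(1 / 6, 6))
  expect_equal(init$mixture$sds, rep(1 / 6, 6))
  init4 <- init_fusion(src, n_components = 4)
  expect_equal(init4$mixture$means, c(-2, 0, 2, 4))
  # affine parameters are the per-source z-score coefficients
  expect_equal(init$source_models[[1]]$a, sd(src[[1]]$values))
  expect_equal(init$source_models[[2]]$b, mean(src[[2]]$values))
  flat <- source_series("flat", "stress", "u", rep(2, 5))
  expect_error(init_fusion(list(flat)), "zero variance")
})

test_that("source density is the Jacobian-scaled latent density", {
  mix <- latent_mixture(c(0.3, 0.7), c(-1, 2), c(0.5, 1))
  d <- seq(-4, 6, length.out = 11)
  ident <- affine_source_model(1, 0)
  expect_equal(source_density(d, ident, mix),
               perfdens:::mixture_density(mix, d))
  th <- affine_source_model(2, 3)
  s <- 0.7
  expect_equal(source_density(2 * s + 3, th, mix),
               perfdens:::mixture_density(mix, s) / 2)
  g <- seq(3 - 20, 3 + 20, length.out = 20001)
  expect_equal(perfdens:::trapz(g, source_density(g, th, mix)), 1,
               tolerance = 1e-4)
})

test_that("negative log-likelihood matches closed form and a naive loop", {
  mix1 <- latent_mixture(1, 0.8, 0.6)
  m <- perfdens:::new_fusion_model(list(affine_source_model(1, 0)), mix1,
                                   fitted = FALSE)
  one <- list(source_series("s", "stress", "u", 0.8))
  expect_equal(negative_log_likelihood(m, one),
               -log(1 / (0.6 * sqrt(2 * pi))), tolerance = 1e-12)

  src <- make_sources(seed = 13, n = c(50, 50))
  init <- init_fusion(src, 4)
  nll <- negative_log_likelihood(init, src)
  dup <- lapply(src, function(s)
    source_series(s$source_id, s$variable, s$unit, rep(s$values, 2)))
  expect_equal(negative_log_likelihood(init, dup), 2 * nll,
               tolerance = 1e-9)
  # brute-force per-point oracle
  naive <- 0
  for (i in seq_along(src)) {
    th <- init$source_models[[i]]
    for (v in src[[i]]$values) {
      p <- 0
      for (c in seq_along(init$mixture$weights))
        p <- p + init$mixture$weights[c] *
          dnorm((v - th$b) / th$a, init$mixture$means[c],
                init$mixture$sds[c]) / abs(th$a)
      naive <- naive - log(p)
    }
  }
  expect_equal(nll, naive, tolerance = 1e-9)
})

test_that("joint ML fit descends, is deterministic and stays feasible", {
  src <- make_sources(seed = 21, n = c(150, 150))
  fit1 <- fit_latent_fusion(src, n_components = 4, maxit = 200)
  fit2 <- fit_latent_fusion(src, n_components = 4, maxit = 200)
  init <- init_fusion(src, 4)
  expect_lte(fit1$nll, negative_log_likelihood(init, src))
  expect_identical(coef(fit1), coef(fit2))
  expect_equal(sum(fit1$mixture$weights), 1, tolerance = 1e-9)
  expect_true(all(fit1$mixture$sds >= 1e-3))
  # anchored source keeps its initialization
  expect_identical(fit1$source_models[[1]]$a, init$source_models[[1]]$a)
  expect_identical(fit1$source_models[[1]]$b, init$source_models[[1]]$b)
})

test_that("objective is invariant under the latent affine indeterminacy", {
  src <- make_sources(seed = 8, n = c(60, 60))
  fit <- fit_latent_fusion(src, n_components = 4, maxit = 100)
  nll <- negative_log_likelihood(fit, src)
  kappa <- 1.3; delta <- 0.4        # s -> kappa*s + delta, compensated
  repar <- fit
  repar$source_models <- lapply(fit$source_models, function(t)
    affine_source_model(t$a * kappa, t$b + t$a * delta))
  repar$mixture <- latent_mixture(fit$mixture$weights,
                                  (fit$mixture$means - delta) / kappa,
                                  fit$mixture$sds / kappa)
  expect_equal(negative_log_likelihood(repar, src), nll, tolerance = 1e-9)
})

test_that("fused marginal tabulates the latent mixture exactly", {
  mix <- latent_mixture(c(0.2, 0.5, 0.3), c(-1, 0.5, 2), c(0.4, 0.7, 0.5))
  m <- perfdens:::new_fusion_model(list(affine_source_model(1, 0)), mix,
                                   fitted = TRUE)
  fm <- fused_marginal(m)
  expect_equal(perfdens:::trapz(fm$grid, fm$density), 1, tolerance = 1e-6)
  naive <- numeric(length(fm$grid))
  for (c in 1:3)
    naive <- naive + mix$weights[c] * dnorm(fm$grid, mix$means[c],
                                            mix$sds[c])
  expect_equal(fm$density, naive / perfdens:::trapz(fm$grid, naive),
               tolerance = 1e-12)
  single <- perfdens:::new_fusion_model(
    list(affine_source_model(1, 0)), latent_mixture(1, 1.5, 0.8), TRUE)
  fs <- fused_marginal(single)
  expect_equal(fs$grid[which.max(fs$density)], 1.5, tolerance = 0.01)
})

test_that("fusion model JSON serialization round-trips", {
  src <- make_sources()
  init <- init_fusion(src, 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_fusion_model(init, f)
  back <- read_fusion_model(f)
  expect_equal(coef(back), coef(init), tolerance = 1e-12)
  expect_equal(back$anchor, 1L)
})
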