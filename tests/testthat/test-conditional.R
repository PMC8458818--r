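test_that("conditioning a single-component model returns its outcome margin", {
  model <- fx_small_model()
  top <- which.max(model$alpha_val)
  single <- model
  single$alpha_idx <- model$alpha_idx[top]
  single$alpha_val <- 1
  single$nnz <- 1L
  mu <- perfdens:::basis_mu(model$basis, single$alpha_idx)
  sig <- perfdens:::basis_sigma(model$basis, single$alpha_idx)
  for (x in list(c(0, 0, 0), c(0.5, -0.5, 0.9), c(-1, 1, -1))) {
    cd <- condition(single, x)
    expect_equal(cd$weights, 1)
    expect_equal(cd$pdf$density,
                 dnorm(cd$pdf$grid, mu[, 1], sig) /
                   perfdens:::trapz(cd$pdf$grid, dnorm(cd$pdf$grid, mu[, 1],
                                                       sig)),
                 tolerance = 1e-9)
  }
})

test_that("closed-form conditionals match direct quadrature of the ratio", {
  model <- fx_small_model()
  a <- perfdens:::joint_alpha(model)
  for (x0 in list(c(0.2, -0.3, 0.1), c(-0.6, 0.4, 0.8))) {
    cd <- condition(model, x0)
    expect_equal(perfdens:::trapz(cd$pdf$grid, cd$pdf$density), 1,
                 tolerance = 1e-6)
    expect_equal(sum(cd$weights), 1, tolerance = 1e-9)
    expect_gte(min(cd$weights), 0)
    yg <- cd$pdf$grid
    pts <- cbind(yg, matrix(rep(x0, each = length(yg)), ncol = 3))
    num <- as.vector(eval_basis(model$basis, pts) %*% a)
    oracle <- num / perfdens:::trapz(yg, num)
    expect_lt(max(abs(cd$pdf$density - oracle)), 1e-4)
  }
})

test_that("points outside the modeled support are rejected or clamped", {
  model <- fx_small_model()
  expect_warning(cd <- condition(model, c(1.5, 0, 0)), "clamping")
  expect_equal(cd$x[1], 1)
  # a model so tight that a far corner underflows every component
  b <- build_basis(3, c(0.01, 0.02))
  corner <- which(apply(b$centers, 1, function(r) all(r == 1)))
  tight <- structure(list(basis = b, alpha_idx = corner, alpha_val = 1,
                          nnz = 1L, transforms = rep(list(NULL), 4),
                          r_targets = NULL, supplied = NULL,
                          variables = NULL, outcome = NULL,
                          moments_supplied = NULL, config = list(),
                          diagnostics = list()),
                     class = "joint_density")
  expect_error(condition(tight, c(-1, -1, -1)), "outside model support")
})

test_that("summaries of a tabulated Gaussian match its closed forms", {
  g <- seq(-8, 8, length.out = 2001)
  s <- summarize_conditional(grid_pdf(g, dnorm(g)))
  expect_equal(s$mean, 0, tolerance = 1e-3)
  expect_equal(s$median, 0, tolerance = 1e-3)
  expect_equal(s$mode, 0, tolerance = 1e-3)
  expect_equal(s$skew, 0, tolerance = 1e-2)
  expect_equal(s$excess_kurtosis, 0, tolerance = 1e-2)
  expect_equal(unname(s$interval), c(-1.96, 1.96), tolerance = 0.01)
  expect_true(all(diff(s$percentiles) > 0))
})

test_that("mixture summaries respect linearity of expectation", {
  g <- seq(-10, 14, length.out = 4001)
  w <- c(0.3, 0.7); mus <- c(-2, 5); sds <- c(1, 1.5)
  d <- w[1] * dnorm(g, mus[1], sds[1]) + w[2] * dnorm(g, mus[2], sds[2])
  s <- summarize_conditional(grid_pdf(g, d / perfdens:::trapz(g, d)))
  expect_equal(s$mean, sum(w * mus), tolerance = 1e-6)
})

test_that("summaries are stable under grid refinement", {
  model <- fx_small_model()
  x0 <- c(0.1, 0.2, -0.4)
  s1 <- summarize_conditional(condition(model, x0, n_grid = 512L))
  s2 <- summarize_conditional(condition(model, x0, n_grid = 1024L))
  for (f in c("mean", "sd", "mode", "median", "skew", "excess_kurtosis"))
    expect_lt(abs(s1[[f]] - s2[[f]]), 1e-3)
  expect_lt(max(abs(s1$interval - s2$interval)), 1e-3)
})

test_that("summaries report physical units through the axis transform", {
  model <- fx_small_model()
  model$transforms[[1]] <- axis_transform(200, 600)   # e.g. milliseconds
  cd <- condition(model, c(0, 0, 0))
  s_norm <- summarize_conditional(structure(
    list(pdf = grid_pdf(cd$pdf$grid, cd$pdf$density), weights = cd$weights,
         x = cd$x), class = "conditional_density"))
  s_phys <- summarize_conditional(cd)
  expect_equal(s_phys$mean, to_physical(model$transforms[[1]], s_norm$mean),
               tolerance = 1e-6)
  expect_equal(s_phys$sd, s_norm$sd * 200, tolerance = 1e-6)
  expect_equal(s_phys$skew, s_norm$skew, tolerance = 1e-6)
})

test_that("conditional means are unbiased for sampled outcomes (tower property)", {
  model <- fx_small_model()
  smp <- sample_joint(model, 1e4, seed = 15)
  inside <- utils::head(which(apply(abs(smp[, 2:4]) <= 1, 1, all)), 1500)
  resid <- vapply(inside, function(i) {
    cd <- condition(model, smp[i, 2:4])
    smp[i, 1] - perfdens:::trapz(cd$pdf$grid, cd$pdf$grid * cd$pdf$density)
  }, numeric(1))
  # E[y - E(y|x)] = 0 exactly, also conditional on x staying in the box
  se <- sd(resid) / sqrt(length(resid))
  expect_lt(abs(mean(resid)), 3 * se)
})

test_that("predict and batch_predict wrap conditioning deterministically", {
  model <- fx_small_model()
  model$outcome <- "y"
  out <- predict(model, rbind(c(0, 0, 0), c(0.3, -0.3, 0.3)))
  expect_equal(nrow(out), 2)
  bp <- batch_predict(list(model, model, model), c(0.1, 0.1, 0.1))
  expect_equal(nrow(bp), 3)
  expect_equal(bp$mean[1], bp$mean[2])
  expect_equal(bp$mean[2], bp$mean[3])
  # mismatched predictor transforms are refused
  other <- model
  other$transforms[[2]] <- axis_transform(0, 1)
  expect_error(batch_predict(list(model, other, model), c(0, 0, 0)),
               "disagree")
})
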