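test_that("reweighted sparsification recovers a representable problem", {
  b <- build_basis(5, c(0.1, 0.2, 0.3))
  gr <- gen_representable_joint(b, nnz = 10, seed = 2)
  model <- adaptive_sparsify(gr$system, lam = 1e-7, target_nnz = 40)
  expect_lte(model$nnz, 40)
  expect_equal(sum(model$alpha_val), 1, tolerance = 1e-6)
  fid <- recovered_stats(model)
  # recovered marginals vs the exact targets of the generating alpha
  ev <- gr$system$eval_points
  for (ax in 1:4) {
    rec <- approx(fid$marginals[[ax]]$grid, fid$marginals[[ax]]$density,
                  xout = ev)$y
    l1 <- perfdens:::trapz(ev, abs(rec - gr$system$targets[[ax]]))
    expect_lte(l1, 0.02)
  }
})

test_that("unreachable sparsity targets return the best iterate with warning", {
  b <- build_basis(3, c(0.1, 0.2))
  gr <- gen_representable_joint(b, nnz = 12, seed = 6)
  expect_warning(
    model <- adaptive_sparsify(gr$system, lam = 1e-12, target_nnz = 1L,
                               max_outer = 2L),
    "sparsity target")
  expect_false(model$diagnostics$sparsity_met)
  expect_equal(sum(model$alpha_val), 1, tolerance = 1e-9)
})

test_that("recovered moments and correlations follow the mixture algebra", {
  model <- fx_small_model()
  fid <- recovered_stats(model)
  comp <- perfdens:::joint_components(model)
  for (ax in 1:4)
    expect_equal(perfdens:::trapz(fid$marginals[[ax]]$grid,
                                  fid$marginals[[ax]]$density), 1,
                 tolerance = 1e-4)
  # sampling oracle for the algebraic correlation
  smp <- sample_joint(model, 1e5, seed = 44)
  for (j in 1:3) {
    r_emp <- cor(smp[, j + 1], smp[, 1])
    se <- (1 - fid$r_recovered[j]^2) / sqrt(1e5)
    expect_lt(abs(r_emp - fid$r_recovered[j]), 3 * se)
  }
})

test_that("a moment-free fit of symmetric targets has no correlation", {
  b <- build_basis(3, c(0.15, 0.3))
  ev <- seq(-1, 1, length.out = 21)
  sym <- dnorm(ev, 0, 0.35)
  marg <- lapply(1:4, function(a)
    grid_pdf(ev, sym / perfdens:::trapz(ev, sym)))
  system <- constraint_system(b, marg, r_targets = c(0.4, -0.2, 0.3),
                              k_points = 21,
                              block_weights = c(1, 1, 1, 1, 0))
  model <- adaptive_sparsify(system, lam = 1e-6, target_nnz = 200)
  fid <- recovered_stats(model)
  expect_true(all(abs(fid$r_recovered) < 0.02))
})

test_that("slices are nonnegative, peak correctly and integrate consistently", {
  model <- fx_small_model()
  comp <- perfdens:::joint_components(model)
  top <- which.max(comp$weight)
  # a slice through a single-component model peaks at the component center
  single <- model
  single$alpha_idx <- model$alpha_idx[top]
  single$alpha_val <- 1
  single$nnz <- 1L
  g <- seq(-1.5, 1.5, length.out = 121)
  sl <- eval_slice(single, fixed = c("3" = comp$mu[top, 3],
                                     "4" = comp$mu[top, 4]),
                   free_grids = list(g, g))
  pk <- which(sl == max(sl), arr.ind = TRUE)
  expect_equal(g[pk[1]], comp$mu[top, 1], tolerance = 0.03)
  expect_equal(g[pk[2]], comp$mu[top, 2], tolerance = 0.03)
  expect_true(all(sl >= 0))
  # integrating the slice over its free axes recovers the fixed-axes margin
  gg <- seq(-2.5, 2.5, length.out = 161)
  x2fix <- 0.21
  sl3 <- eval_slice(model, fixed = c("2" = x2fix),
                    free_grids = list(gg, gg, gg))
  dx <- gg[2] - gg[1]
  integ <- sum(sl3) * dx^3
  direct <- sum(comp$weight * dnorm(x2fix, comp$mu[, 2], comp$sigma))
  expect_equal(integ, direct, tolerance = 1e-3)
})

test_that("fitted joints conserve mass and keep it in the modeled box", {
  # components are exact Gaussian PDFs: total mass equals the coefficient
  # sum exactly, and for a fit to interior marginals nearly all of it
  # stays inside [-1, 1]^4 (the widest component sd is 0.4)
  model <- fx_joint("reaction_time")
  comp <- perfdens:::joint_components(model)
  expect_equal(sum(comp$weight), 1, tolerance = 1e-6)
  box_mass <- vapply(seq_along(comp$weight), function(i)
    prod(pnorm(1, comp$mu[i, ], comp$sigma[i]) -
           pnorm(-1, comp$mu[i, ], comp$sigma[i])), numeric(1))
  expect_equal(sum(comp$weight * box_mass), 1, tolerance = 0.05)
})

test_that("joint model serialization round-trips sparse coefficients", {
  model <- fx_small_model()
  model$transforms <- list(axis_transform(100, 700), axis_transform(-2, 4),
                           axis_transform(2, 11), axis_transform(6, 20))
  f <- withr::local_tempfile(fileext = ".csv")
  write_joint_density(model, f)
  back <- read_joint_density(f)
  expect_identical(back$alpha_idx, model$alpha_idx)
  expect_equal(back$alpha_val, model$alpha_val, tolerance = 1e-15)
  expect_equal(back$basis$widths, model$basis$widths)
  expect_equal(back$transforms[[1]]$physical_hi, 700)
  fid_a <- recovered_stats(model)
  fid_b <- recovered_stats(back)
  expect_equal(fid_b$r_recovered, unname(fid_a$r_recovered),
               tolerance = 1e-12, ignore_attr = TRUE)
})
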