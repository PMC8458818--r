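test_that("lattice geometry follows the stated ordering and counts", {
  b <- build_basis(3, c(0.1, 0.2))
  expect_equal(b$basis_count, 162)
  expect_equal(length(build_basis(3)$widths), 7)
  expect_equal(build_basis(5)$axis_points, c(-1, -0.5, 0, 0.5, 1))
  expect_error(build_basis(4), "odd")
  expect_error(build_basis(3, c(0.2, 0.1)), "increasing")
  # width-major indexing: component 1 and component 82 share a center
  expect_equal(perfdens:::basis_mu(b, 1), perfdens:::basis_mu(b, 82))
  expect_equal(perfdens:::basis_sigma(b, 1), 0.1)
  expect_equal(perfdens:::basis_sigma(b, 82), 0.2)
})

test_that("basis functions have the isotropic Gaussian peak and symmetry", {
  b <- build_basis(3, c(0.15, 0.3))
  i <- 47L
  mu <- perfdens:::basis_mu(b, i)
  sig <- perfdens:::basis_sigma(b, i)
  at_peak <- eval_basis(b, mu, idx = i)
  expect_equal(as.numeric(at_peak), 1 / ((2 * pi)^2 * sig^4),
               tolerance = 1e-12)
  u <- c(0.07, -0.12, 0.05, 0.2)
  expect_equal(eval_basis(b, mu + u, idx = i), eval_basis(b, mu - u, idx = i),
               tolerance = 1e-12)
})

test_that("a single basis function integrates to one (Monte Carlo)", {
  b <- build_basis(3, c(0.2))
  i <- 41L                               # the center at the origin
  mu <- as.numeric(perfdens:::basis_mu(b, i))
  sig <- perfdens:::basis_sigma(b, i)
  set.seed(100)
  half <- 5 * sig
  pts <- sweep(matrix(runif(4 * 1e6, -half, half), ncol = 4), 2, mu, "+")
  vol <- (2 * half)^4
  est <- mean(eval_basis(b, pts, idx = i)) * vol
  expect_equal(est, 1, tolerance = 0.02)
})

test_that("marginal design rows are the univariate component Gaussians", {
  b <- build_basis(3, c(0.1, 0.2))
  ev <- seq(-1, 1, length.out = 21)
  A <- marginal_design(b, 2, ev)
  # uniform coefficients on a symmetric basis give a symmetric marginal
  marg <- as.vector(A %*% rep(1 / b$basis_count, b$basis_count))
  expect_equal(marg, rev(marg), tolerance = 1e-12)
  # one nonzero coefficient reproduces that component's Gaussian
  i <- 100L
  a1 <- numeric(b$basis_count); a1[i] <- 1
  expect_equal(as.vector(A %*% a1),
               dnorm(ev, perfdens:::basis_mu(b, i)[, 2],
                     perfdens:::basis_sigma(b, i)),
               tolerance = 1e-12)
})

test_that("implied marginals of sparse coefficients integrate to one", {
  b <- build_basis(5, c(0.1, 0.2, 0.3))
  gr <- gen_representable_joint(b, nnz = 8, seed = 12)
  # evaluate directly from the mixture on a grid wide enough to hold the
  # tails of edge components (marginal_design itself is clamped to [-1,1])
  g <- seq(-3, 3, length.out = 2001)
  comp_idx <- which(gr$alpha > 0)
  dens <- numeric(length(g))
  for (i in comp_idx)
    dens <- dens + gr$alpha[i] *
      dnorm(g, perfdens:::basis_mu(b, i)[, 1], perfdens:::basis_sigma(b, i))
  expect_equal(perfdens:::trapz(g, dens), 1, tolerance = 1e-4)
})

test_that("moment rows reproduce sampled correlations of a known mixture", {
  b <- build_basis(5, c(0.1, 0.2, 0.3))
  gr <- gen_representable_joint(b, nnz = 8, seed = 4)
  # package the true alpha as a joint_density to reuse the sampler
  idx <- which(gr$alpha > 0)
  model <- structure(list(basis = b, alpha_idx = idx,
                          alpha_val = gr$alpha[idx], nnz = length(idx),
                          transforms = rep(list(NULL), 4),
                          r_targets = gr$r_true, supplied = NULL,
                          variables = NULL, outcome = NULL,
                          moments_supplied = gr$moments,
                          config = list(), diagnostics = list()),
                     class = "joint_density")
  smp <- sample_joint(model, 1e5, seed = 6)
  for (j in 1:3) {
    r_emp <- cor(smp[, j + 1], smp[, 1])
    se <- (1 - gr$r_true[j]^2) / sqrt(1e5)
    expect_lt(abs(r_emp - gr$r_true[j]), 3 * se)
  }
  # independence case: single origin-centered component has E[x_j y] = 0
  origin <- (5^4 + 1) / 2                # center index of the origin
  a0 <- numeric(b$basis_count); a0[origin] <- 1
  mom0 <- lapply(1:4, function(a)
    structure(list(mean = 0, sd = 0.2), class = "moment_summary"))
  md <- moment_design(b, mom0, r_targets = c(0, 0, 0))
  expect_equal(as.vector(md$A %*% a0), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(md$target, c(0, 0, 0))
})

test_that("moment design rejects degenerate scales", {
  b <- build_basis(3, c(0.1))
  momz <- lapply(1:4, function(a)
    structure(list(mean = 0, sd = 0), class = "moment_summary"))
  expect_error(moment_design(b, momz, c(0, 0, 0)), "zero sd")
})
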