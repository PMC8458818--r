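test_that("moving-average error rates reproduce windowed means", {
  expect_equal(moving_average_error(c(0, 0, 0, 0, 0), 5), 0)
  expect_equal(moving_average_error(c(1, 1, 1, 1, 1, 1), 5), c(1, 1))
  expect_equal(moving_average_error(c(1, 0, 0, 0, 0), 5), 0.2)
  set.seed(11)
  x <- rbinom(40, 1, 0.3)
  ma <- moving_average_error(x, 5)
  expect_length(ma, 36)
  expect_true(all(ma >= 0 & ma <= 1))
  expect_equal(ma[7], mean(x[7:11]))
  expect_error(moving_average_error(c(0, 1), 5), "shorter than window")
  expect_error(moving_average_error(c(0, 2, 1), 2), "0/1")
})

test_that("pooling weights are sample-size proportions summing to one", {
  s <- function(id, n) source_series(id, "sleep", "hours", seq_len(n))
  expect_identical(pool_weights(list(s("a", 5))), 1)
  expect_equal(pool_weights(list(s("a", 30), s("b", 70))), c(0.3, 0.7))
  w <- pool_weights(list(s("a", 17), s("b", 17), s("c", 17)))
  expect_equal(w, rep(1 / 3, 3))
  expect_identical(sum(w), 1)
  bad <- list(s("a", 3), source_series("b", "stress", "hours", 1:3))
  expect_error(pool_weights(bad), "mix variables")
  expect_error(pool_weights(list()), "non-empty")
})

test_that("unit conversion is an invertible affine map on the values", {
  s <- source_series("lab1", "stress", "ug/dL", c(0.5, 1, 2.3))
  expect_equal(convert_units(s, 1, 0)$values, s$values)
  nm <- convert_units(s, factor = 27.59, new_unit = "nmol/L")
  expect_equal(nm$values[2], 27.59)
  expect_identical(nm$unit, "nmol/L")
  back <- convert_units(nm, 1 / 27.59, new_unit = "ug/dL")
  expect_equal(back$values, s$values, tolerance = 1e-9)
  expect_error(convert_units(s, 0), "nonzero")
})

test_that("pooled KDE recovers moments of seeded draws and normalizes", {
  set.seed(42)
  x <- rnorm(1000)
  src <- source_series("sim", "reaction_time", "ms", x)
  est <- estimate_marginal(list(src))
  expect_equal(perfdens:::trapz(est$grid, est$density), 1, tolerance = 1e-6)
  mm <- moments(est)
  expect_lt(abs(mm$mean - mean(x)), 0.1)
  expect_lt(abs(mm$sd - sd(x)), 0.1)
})

test_that("single-source pooled estimate equals the plain KDE pointwise", {
  set.seed(5)
  x <- rgamma(200, 3, 1)
  src <- source_series("g", "exertion", "borg", x)
  est <- estimate_marginal(list(src))
  # independent oracle: direct sum of Gaussian kernels at Scott bandwidth
  bw <- sd(x) * length(x)^(-1 / 5)
  direct <- vapply(est$grid, function(g) mean(dnorm(g, x, bw)), numeric(1))
  direct <- direct / perfdens:::trapz(est$grid, direct)
  expect_equal(est$density, direct, tolerance = 1e-12)
})

test_that("well-separated sources give a bimodal pooled density", {
  set.seed(9)
  a <- rnorm(400, -4, 0.7)
  b <- rnorm(400, 4, 0.7)
  est <- estimate_marginal(list(source_series("a", "sleep", "hours", a),
                                source_series("b", "sleep", "hours", b)))
  # oracle: direct weighted KDE evaluation near the two source means
  bwa <- sd(a) * 400^(-1 / 5); bwb <- sd(b) * 400^(-1 / 5)
  kde2 <- function(g) 0.5 * mean(dnorm(g, a, bwa)) +
    0.5 * mean(dnorm(g, b, bwb))
  d <- est$density
  peaks <- est$grid[which(diff(sign(diff(d))) == -2) + 1]
  expect_length(peaks, 2)
  expect_lt(abs(peaks[1] - mean(a)), bwa)
  expect_lt(abs(peaks[2] - mean(b)), bwb)
  at_peaks <- approx(est$grid, d, xout = peaks)$y
  z <- perfdens:::trapz
  expect_equal(at_peaks * z(est$grid, vapply(est$grid, kde2, numeric(1))),
               vapply(peaks, kde2, numeric(1)), tolerance = 1e-6)
})

test_that("degenerate sources are rejected", {
  cst <- source_series("c", "sleep", "hours", rep(3, 10))
  expect_error(estimate_marginal(list(cst)), "degenerate")
})

test_that("packaged conversion table drives unit conversion", {
  conv <- default_unit_conversions()
  row <- conv[conv$variable == "stress" & conv$from_unit == "ug/dL", ]
  expect_equal(row$factor, 27.59)
  s <- source_series("lab", "stress", "ug/dL", c(0.4, 1))
  out <- convert_units(s, row$factor, row$offset, new_unit = row$to_unit)
  expect_equal(out$values, c(0.4, 1) * 27.59)
  inv <- conv[conv$variable == "stress" & conv$from_unit == "nmol/L", ]
  back <- convert_units(out, inv$factor, inv$offset, new_unit = "ug/dL")
  expect_equal(back$values, s$values, tolerance = 1e-4)
})

test_that("observation CSV round-trips source series", {
  src <- list(source_series("s1", "sleep", "hours", c(6.5, 7, 8)),
              source_series("s2", "sleep", "hours", c(5, 5.5)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_source_csv(src, f)
  back <- read_source_csv(f, variable = "sleep")
  expect_length(back, 2)
  ns <- vapply(back, `[[`, integer(1), "n")
  expect_setequal(ns, c(3L, 2L))
  expect_error(read_source_csv(f, variable = "stress"), "no rows")
})
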