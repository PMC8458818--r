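#' Trapezoidal integral of tabulated values
#'
#' @param x strictly increasing abscissae.
#' @param y values of the integrand at `x`.
#' @return The trapezoid-rule integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Row-wise log-sum-exp
#'
#' Numerically stable log(sum(exp(m[i, ]))) per row.
#' @param m numeric matrix.
#' @return numeric vector, one value per row.
#' @keywords internal
log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
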