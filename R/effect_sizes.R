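#' Convert a standardized effect size to a correlation coefficient
#'
#' Standardized mean differences (Cohen's d, Hedges' g) are converted to
#' the point-biserial correlation r = d / sqrt(d^2 + a), where
#' a = (n1 + n2)^2 / (n1 * n2) reduces to 4 for equal group sizes.  A
#' correlation input passes through unchanged.
#'
#' @param value the effect size value.
#' @param measure one of "cohens_d", "hedges_g", "r".
#' @param n1,n2 group sizes (optional; equal groups assumed when absent).
#' @return A correlation in (-1, 1), sign preserved.
#' @examples
#' to_correlation(1, "cohens_d")   # 0.4472136
#' to_correlation(0.3, "r")        # 0.3
#' @export
to_correlation <- function(value, measure = c("r", "cohens_d", "hedges_g"),
                           n1 = NULL, n2 = NULL) {
  measure <- match.arg(measure)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  if (measure == "r") {
    if (abs(value) >= 1)
      stopf("to_correlation: |r| = %g must be < 1", abs(value))
    return(value)
  }
  # Hedges' g is treated as d; its small-sample correction factor is a
  # multiplicative constant that the point-biserial map absorbs only if
  # degrees of freedom are known, which the input format does not carry.
  a <- if (is.null(n1) || is.null(n2)) 4
  else {
    if (n1 < 2 || n2 < 2) stopf("to_correlation: group sizes must be >= 2")
    (n1 + n2)^2 / (n1 * n2)
  }
  value / sqrt(value^2 + a)
}

#' One literature effect-size entry (predictor-outcome correlation)
#'
#' @param predictor,outcome variable names.
#' @param r correlation in (-1, 1).
#' @param ci_lo,ci_hi 95% confidence bounds with `ci_lo <= r <= ci_hi`.
#' @return An object of class `effect_size_entry`.
#' @export
effect_size_entry <- function(predictor, outcome, r, ci_lo, ci_hi) {
  stopifnot(is.character(predictor), is.character(outcome))
  if (abs(r) >= 1) stopf("effect_size_entry: |r| must be < 1")
  if (!(ci_lo <= r && r <= ci_hi))
    stopf("effect_size_entry: need ci_lo <= r <= ci_hi (got %g, %g, %g)",
          ci_lo, r, ci_hi)
  structure(list(predictor = predictor, outcome = outcome, r = r,
                 ci_lo = ci_lo, ci_hi = ci_hi),
            class = "effect_size_entry")
}

fisher_z <- function(r) atanh(r)
fisher_z_inv <- function(z) tanh(z)

#' Pool effect sizes for one predictor-outcome pair
#'
#' Inverse-variance-weighted mean on the Fisher-z scale, back-transformed;
#' the pooled confidence interval comes from the pooled z-variance.  With
#' study sizes `n` the z-variance is 1/(n - 3); without them, entries are
#' weighted equally and the pooled variance is the mean of the
#' CI-implied variances.
#'
#' @param entries list of [effect_size_entry] for the same pair.
#' @param n optional per-entry study sizes (inverse-variance weights).
#' @param level confidence level of the output interval.
#' @return One pooled [effect_size_entry].
#' @export
aggregate_effect_sizes <- function(entries, n = NULL, level = 0.95) {
  if (!is.list(entries) || length(entries) == 0L)
    stopf("aggregate_effect_sizes: empty entry list")
  ok <- vapply(entries, inherits, logical(1), "effect_size_entry")
  if (!all(ok)) stopf("aggregate_effect_sizes: entries must be effect_size_entry")
  pairs <- unique(vapply(entries, function(e)
    paste(e$predictor, e$outcome, sep = "->"), character(1)))
  if (length(pairs) != 1L)
    stopf("aggregate_effect_sizes: mixed pairs: %s",
          paste(pairs, collapse = "; "))
  if (length(entries) == 1L) return(entries[[1]])
  z <- vapply(entries, function(e) fisher_z(e$r), numeric(1))
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  if (is.null(n)) {
    w <- rep(1, length(entries))
    vz <- vapply(entries, function(e)
      ((fisher_z(e$ci_hi) - fisher_z(e$ci_lo)) / (2 * zcrit))^2, numeric(1))
    v_pooled <- mean(vz) / length(entries)
  } else {
    stopifnot(length(n) == length(entries), all(n > 3))
    w <- n - 3
    v_pooled <- 1 / sum(w)
  }
  zbar <- sum(w * z) / sum(w)
  half <- zcrit * sqrt(v_pooled)
  effect_size_entry(entries[[1]]$predictor, entries[[1]]$outcome,
                    r = fisher_z_inv(zbar),
                    ci_lo = fisher_z_inv(zbar - half),
                    ci_hi = fisher_z_inv(zbar + half))
}

#' The 3 x 3 predictor-outcome effect-size matrix
#'
#' @param entries list of [effect_size_entry], one per requested
#'   predictor-outcome pair, no duplicates.
#' @param predictors,outcomes the variable names the matrix must cover.
#' @return An object of class `effect_size_matrix`.
#' @export
effect_size_matrix <- function(entries,
                               predictors = c("stress", "sleep", "exertion"),
                               outcomes = c("reaction_time",
                                            "executive_function",
                                            "perceptuo_motor")) {
  keys <- vapply(entries, function(e)
    paste(e$predictor, e$outcome, sep = "->"), character(1))
  if (anyDuplicated(keys))
    stopf("effect_size_matrix: duplicate pair %s", keys[duplicated(keys)][1])
  want <- as.vector(outer(predictors, outcomes, paste, sep = "->"))
  missing <- setdiff(want, keys)
  if (length(missing))
    stopf("effect_size_matrix: missing pair(s): %s",
          paste(missing, collapse = ", "))
  names(entries) <- keys
  structure(list(entries = entries, predictors = predictors,
                 outcomes = outcomes),
            class = "effect_size_matrix")
}

#' Look up one entry of an effect-size matrix
#'
#' @param esm an [effect_size_matrix].
#' @param predictor,outcome variable names.
#' @return The matching [effect_size_entry].
#' @export
effect_size <- function(esm, predictor, outcome) {
  stopifnot(inherits(esm, "effect_size_matrix"))
  key <- paste(predictor, outcome, sep = "->")
  e <- esm$entries[[key]]
  if (is.null(e)) stopf("effect_size: no entry for %s", key)
  e
}

#' @export
print.effect_size_matrix <- function(x, ...) {
  m <- sapply(x$outcomes, function(o) sapply(x$predictors, function(p)
    effect_size(x, p, o)$r))
  cat("effect_size_matrix (r):\n")
  print(round(m, 3))
  invisible(x)
}

#' Packaged literature effect sizes for the six-variable system
#'
#' The default predictor-outcome correlation matrix (with 95% confidence
#' intervals) aggregated from meta-analyses and original studies relating
#' stress, sleep duration and physical exertion to reaction time,
#' executive-function error and perceptuo-motor error.  Note the published
#' supplied-vs-recovered comparison table lists two of these values with a
#' small transcription difference (sleep/reaction-time -0.276 vs the
#' canonical -0.278 used here, sleep/executive-function -0.187 vs -0.183);
#' this function returns the canonical effect-size table.
#'
#' @return An [effect_size_matrix] with all nine pairs.
#' @examples
#' effect_size(default_effect_sizes(), "stress", "reaction_time")$r  # 0.220
#' @export
default_effect_sizes <- function() {
  e <- function(p, o, r, lo, hi) effect_size_entry(p, o, r, lo, hi)
  effect_size_matrix(list(
    e("stress",   "reaction_time",       0.220,  0.157,  0.283),
    e("stress",   "executive_function",  0.091, -0.006,  0.188),
    e("stress",   "perceptuo_motor",     0.459,  0.395,  0.523),
    e("sleep",    "reaction_time",      -0.278, -0.363, -0.193),
    e("sleep",    "executive_function", -0.183, -0.251, -0.115),
    e("sleep",    "perceptuo_motor",    -0.189, -0.334, -0.044),
    e("exertion", "reaction_time",      -0.053, -0.156,  0.050),
    e("exertion", "executive_function", -0.074, -0.154,  0.006),
    e("exertion", "perceptuo_motor",     0.578,  0.223,  0.933)))
}

#' Read / write effect sizes as CSV
#'
#' Columns: `predictor,outcome,measure,value,n1,n2,ci_lo,ci_hi,source_tag`.
#' Non-r measures are converted through [to_correlation] on read; their CI
#' bounds are interpreted on the same measure scale and converted too.
#'
#' @param path CSV file path.
#' @return `read_effect_size_csv` returns an [effect_size_matrix];
#'   `write_effect_size_csv` returns `path` invisibly.
#' @export
read_effect_size_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("predictor", "outcome", "measure", "value", "ci_lo", "ci_hi")
  if (!all(need %in% names(df)))
    stopf("read_effect_size_csv: %s must have columns %s", path,
          paste(need, collapse = ","))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    n1 <- if ("n1" %in% names(df) && is.finite(row$n1)) row$n1
    n2 <- if ("n2" %in% names(df) && is.finite(row$n2)) row$n2
    effect_size_entry(row$predictor, row$outcome,
                      to_correlation(row$value, row$measure, n1, n2),
                      to_correlation(row$ci_lo, row$measure, n1, n2),
                      to_correlation(row$ci_hi, row$measure, n1, n2))
  })
  effect_size_matrix(entries,
                     predictors = unique(df$predictor),
                     outcomes = unique(df$outcome))
}

#' @rdname read_effect_size_csv
#' @param esm an [effect_size_matrix].
#' @export
write_effect_size_csv <- function(esm, path) {
  stopifnot(inherits(esm, "effect_size_matrix"))
  rows <- do.call(rbind, lapply(esm$entries, function(e)
    data.frame(predictor = e$predictor, outcome = e$outcome, measure = "r",
               value = e$r, n1 = NA, n2 = NA, ci_lo = e$ci_lo,
               ci_hi = e$ci_hi, source_tag = "")))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
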