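#' A single data source's observations of one variable
#'
#' @param source_id short text label for the originating study or dataset.
#' @param variable one of the six pipeline variables (e.g. "reaction_time").
#' @param unit text unit label (e.g. "ms", "hours", "borg", "proportion").
#' @param values finite numeric observations, length >= 1.
#' @return An object of class `source_series` with an `n` field.
#' @export
source_series <- function(source_id, variable, unit, values) {
  stopifnot(is.character(source_id), is.character(variable),
            is.character(unit), is.numeric(values))
  if (length(values) < 1L) stopf("source_series: needs at least one value")
  if (any(!is.finite(values))) stopf("source_series: non-finite values")
  structure(list(source_id = source_id, variable = variable, unit = unit,
                 values = as.numeric(values), n = length(values)),
            class = "source_series")
}

#' @export
print.source_series <- function(x, ...) {
  cat(sprintf("source_series '%s': %d x %s [%s]\n",
              x$source_id, x$n, x$variable, x$unit))
  invisible(x)
}

#' Moving-average error rates from binary trial outcomes
#'
#' Error-rate variables (executive function, perceptuo-motor control) are
#' derived from per-trial correct/incorrect sequences by averaging over a
#' sliding window of successive trials (window of 5 by default), turning a
#' 0/1 sequence into a sequence of local error proportions.
#'
#' @param trial_outcomes numeric vector of 0/1 trial outcomes (1 = error).
#' @param window positive integer window length; must not exceed the
#'   sequence length.
#' @return Numeric vector of length `length(trial_outcomes) - window + 1`,
#'   each entry in \[0, 1\].
#' @examples
#' moving_average_error(c(1, 0, 0, 0, 0), window = 5)  # 0.2
#' @export
moving_average_error <- function(trial_outcomes, window = 5L) {
  stopifnot(is.numeric(trial_outcomes), length(window) == 1L)
  window <- as.integer(window)
  if (window < 1L) stopf("moving_average_error: window must be positive")
  if (length(trial_outcomes) < window)
    stopf("moving_average_error: sequence (%d) shorter than window (%d)",
          length(trial_outcomes), window)
  if (any(!trial_outcomes %in% c(0, 1)))
    stopf("moving_average_error: outcomes must be 0/1")
  cs <- c(0, cumsum(trial_outcomes))
  n <- length(trial_outcomes)
  (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
}

#' Pooling weights proportional to per-source sample sizes
#'
#' When several sources contribute observations of the same variable in the
#' same unit, each source's kernel density estimate enters the pooled
#' marginal with weight equal to its fraction of the total observations.
#'
#' @param sources list of [source_series], all with identical `variable`
#'   and `unit`.
#' @return Numeric weights summing exactly to 1.
#' @export
pool_weights <- function(sources) {
  check_source_list(sources)
  n <- vapply(sources, function(s) s$n, numeric(1))
  n / sum(n)
}

check_source_list <- function(sources) {
  if (!is.list(sources) || length(sources) == 0L)
    stopf("expected a non-empty list of source_series")
  ok <- vapply(sources, inherits, logical(1), what = "source_series")
  if (!all(ok)) stopf("all elements must be source_series objects")
  vars <- unique(vapply(sources, function(s) s$variable, character(1)))
  if (length(vars) != 1L)
    stopf("sources mix variables: %s", paste(vars, collapse = ", "))
  units <- unique(vapply(sources, function(s) s$unit, character(1)))
  if (length(units) != 1L)
    stopf("sources mix units: %s", paste(units, collapse = ", "))
  invisible(TRUE)
}

#' Linear unit conversion of a data source
#'
#' @param series a [source_series].
#' @param factor nonzero multiplicative factor.
#' @param offset additive offset (default 0).
#' @param new_unit unit label for the converted series.
#' @return A [source_series] with `values * factor + offset`.
#' @examples
#' # cortisol ug/dL -> nmol/L
#' s <- source_series("demo", "stress", "ug/dL", 1)
#' convert_units(s, factor = 27.59, new_unit = "nmol/L")$values  # 27.59
#' @export
convert_units <- function(series, factor, offset = 0,
                          new_unit = paste0(series$unit, "*")) {
  stopifnot(inherits(series, "source_series"),
            is.numeric(factor), length(factor) == 1L)
  if (factor == 0) stopf("convert_units: factor must be nonzero")
  source_series(series$source_id, series$variable, new_unit,
                series$values * factor + offset)
}

# Scott's rule bandwidth for a Gaussian kernel in one dimension.
scott_bandwidth <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_real_)
  s * n^(-1 / 5)
}

#' Pooled kernel density estimate over multiple data sources
#'
#' Each source gets its own Gaussian kernel density estimate (Scott's rule
#' bandwidth times `bandwidth_scale`); the pooled marginal is the mixture
#' of the per-source estimates weighted by [pool_weights].  The grid spans
#' the pooled data range padded by three pooled bandwidths.
#'
#' @param sources list of [source_series] in a common unit.
#' @param bandwidth_scale global multiplier on the per-source Scott
#'   bandwidths (the reproducible stand-in for manual tuning).
#' @param n_grid number of grid points.
#' @return A [grid_pdf] on the physical axis.
#' @export
estimate_marginal <- function(sources, bandwidth_scale = 1.0,
                              n_grid = 512L) {
  check_source_list(sources)
  bw <- vapply(sources, function(s) scott_bandwidth(s$values), numeric(1))
  bw <- bw * bandwidth_scale
  if (all(!is.finite(bw)))
    stopf("estimate_marginal: every source is degenerate (constant values)")
  w <- pool_weights(sources)
  # degenerate sources borrow the pooled-average bandwidth
  bw[!is.finite(bw)] <- stats::weighted.mean(bw[is.finite(bw)],
                                             w[is.finite(bw)])
  allv <- unlist(lapply(sources, `[[`, "values"))
  pad <- 3 * stats::weighted.mean(bw, w)
  grid <- seq(min(allv) - pad, max(allv) + pad, length.out = n_grid)
  dens <- numeric(n_grid)
  for (i in seq_along(sources)) {
    dens <- dens + w[i] * kde_eval(sources[[i]]$values, bw[i], grid)
  }
  grid_pdf(grid, dens / trapz(grid, dens))
}

# Gaussian KDE evaluated on a grid; plain sum of kernels.
kde_eval <- function(x, bw, grid) {
  rowMeans(stats::dnorm(outer(grid, x, "-"), sd = bw))
}

#' Packaged default unit-conversion table
#'
#' Conversion factors shipped with the package for the fixture units
#' (e.g. salivary cortisol ug/dL to nmol/L at factor 27.59).  Real
#' analyses supply their own table of the same shape
#' (`variable,from_unit,to_unit,factor,offset`).
#'
#' @param path optional path to a custom conversion table.
#' @return A data.frame of conversions.
#' @export
default_unit_conversions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "unit_conversions.csv",
                        package = "perfdens")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read per-source observation tables from CSV
#'
#' Expected columns: `source_id,variable,unit,value`, one observation per
#' row, header required.
#'
#' @param path CSV file path.
#' @param variable optional filter: keep only this variable.
#' @return A list of [source_series], one per (source_id, variable, unit).
#' @export
read_source_csv <- function(path, variable = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_id", "variable", "unit", "value")
  if (!all(need %in% names(df)))
    stopf("read_source_csv: %s must have columns %s", path,
          paste(need, collapse = ","))
  if (!is.null(variable)) df <- df[df$variable == variable, , drop = FALSE]
  if (nrow(df) == 0L) stopf("read_source_csv: no rows%s in %s",
                            if (is.null(variable)) ""
                            else paste0(" for variable ", variable), path)
  key <- interaction(df$source_id, df$variable, df$unit, drop = TRUE)
  lapply(split(df, key), function(g)
    source_series(g$source_id[1], g$variable[1], g$unit[1], g$value))
}

#' Write a list of source series to the pipeline's observation CSV format
#'
#' @param sources list of [source_series].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_source_csv <- function(sources, path) {
  rows <- do.call(rbind, lapply(sources, function(s)
    data.frame(source_id = s$source_id, variable = s$variable,
               unit = s$unit, value = s$values)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
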