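#' Linear transform between a physical axis and the normalized [-1, 1] axis
#'
#' Joint-density construction happens on axes normalized to \[-1, 1\]; an
#' `axis_transform` records the physical interval that is mapped linearly
#' onto \[-1, 1\] so results can be reported back in physical units
#' (milliseconds, hours, Borg points, proportions).
#'
#' @param physical_lo,physical_hi bounds of the physical interval mapped to
#'   -1 and +1 respectively; `physical_lo < physical_hi`.
#' @return An object of class `axis_transform` with elements `physical_lo`
#'   and `physical_hi`.
#' @examples
#' tr <- axis_transform(0, 10)
#' to_normalized(tr, 5)    # 0
#' to_physical(tr, 0)      # 5
#' @export
axis_transform <- function(physical_lo, physical_hi) {
  stopifnot(is.numeric(physical_lo), is.numeric(physical_hi),
            length(physical_lo) == 1L, length(physical_hi) == 1L,
            is.finite(physical_lo), is.finite(physical_hi))
  if (physical_lo >= physical_hi)
    stopf("axis_transform: physical_lo (%g) must be < physical_hi (%g)",
          physical_lo, physical_hi)
  structure(list(physical_lo = physical_lo, physical_hi = physical_hi),
            class = "axis_transform")
}

#' @rdname axis_transform
#' @param transform an `axis_transform`.
#' @param x numeric values on the physical axis.
#' @export
to_normalized <- function(transform, x) {
  2 * (x - transform$physical_lo) /
    (transform$physical_hi - transform$physical_lo) - 1
}

#' @rdname axis_transform
#' @param z numeric values on the normalized axis.
#' @export
to_physical <- function(transform, z) {
  transform$physical_lo +
    (z + 1) / 2 * (transform$physical_hi - transform$physical_lo)
}

# Jacobian dz/dx of the physical -> normalized map (a constant).
transform_jacobian <- function(transform) {
  2 / (transform$physical_hi - transform$physical_lo)
}

#' A one-dimensional density tabulated on a grid
#'
#' The basic container for every marginal density in the pipeline: a
#' strictly increasing grid, nonnegative density values, and optionally the
#' [axis_transform] linking the (normalized) grid to physical units.  The
#' constructor renormalizes to unit trapezoidal integral and refuses input
#' whose raw integral is off by more than `tol`.
#'
#' @param grid strictly increasing numeric vector, length >= 3.
#' @param density nonnegative numeric vector, same length as `grid`.
#' @param transform an [axis_transform] if `grid` lives on the normalized
#'   axis, or `NULL` if the grid is already in physical units.
#' @param tol maximal allowed deviation of the raw integral from 1 before
#'   renormalization (values are always divided by the exact integral).
#' @return An object of class `grid_pdf`.
#' @export
grid_pdf <- function(grid, density, transform = NULL, tol = 1e-6) {
  stopifnot(is.numeric(grid), is.numeric(density),
            length(grid) == length(density), length(grid) >= 3L)
  if (any(!is.finite(grid)) || any(!is.finite(density)))
    stopf("grid_pdf: grid and density must be finite")
  if (any(diff(grid) <= 0)) stopf("grid_pdf: grid must be strictly increasing")
  if (any(density < 0)) {
    if (min(density) < -1e-12) stopf("grid_pdf: negative density values")
    density <- pmax(density, 0)
  }
  z <- trapz(grid, density)
  if (abs(z - 1) > tol)
    stopf("grid_pdf: density integrates to %.8g, outside 1 +/- %g", z, tol)
  if (!is.null(transform) && !inherits(transform, "axis_transform"))
    stopf("grid_pdf: transform must be an axis_transform or NULL")
  structure(list(grid = grid, density = density / z, transform = transform),
            class = "grid_pdf")
}

#' @export
print.grid_pdf <- function(x, ...) {
  mm <- moments(x)
  cat(sprintf("grid_pdf: %d points on [%.4g, %.4g]%s\n",
              length(x$grid), min(x$grid), max(x$grid),
              if (is.null(x$transform)) " (physical axis)"
              else sprintf(" (normalized; physical [%.4g, %.4g])",
                           x$transform$physical_lo, x$transform$physical_hi)))
  cat(sprintf("  mean %.4g  sd %.4g\n", mm$mean, mm$sd))
  invisible(x)
}

#' @export
plot.grid_pdf <- function(x, ..., xlab = "value", ylab = "density") {
  plot(x$grid, x$density, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Mean and standard deviation of a tabulated density
#'
#' Computed by trapezoidal quadrature on the stored grid.  Errors if the
#' density is not normalized to within `tol`.
#'
#' @param pdf a [grid_pdf].
#' @param tol tolerance on the integral before the moments are trusted.
#' @return A list with elements `mean` and `sd` (class `moment_summary`).
#' @export
moments <- function(pdf, tol = 1e-6) {
  stopifnot(inherits(pdf, "grid_pdf"))
  z <- trapz(pdf$grid, pdf$density)
  if (abs(z - 1) > tol)
    stopf("moments: density integrates to %.8g, outside 1 +/- %g", z, tol)
  m <- trapz(pdf$grid, pdf$grid * pdf$density) / z
  v <- trapz(pdf$grid, (pdf$grid - m)^2 * pdf$density) / z
  if (v <= 0) stopf("moments: nonpositive variance (degenerate density)")
  structure(list(mean = m, sd = sqrt(v)), class = "moment_summary")
}

#' Quantiles of a tabulated density via the inverse CDF
#'
#' @param pdf a [grid_pdf].
#' @param p probability levels in (0, 1).
#' @return Numeric vector of quantiles (on the grid's own axis).
#' @keywords internal
grid_pdf_quantile <- function(pdf, p) {
  g <- pdf$grid; d <- pdf$density
  n <- length(g)
  cdf <- c(0, cumsum((g[-1] - g[-n]) * (d[-1] + d[-n]) / 2))
  cdf <- cdf / cdf[n]
  # make strictly monotone for interpolation over flat regions
  vapply(p, function(pp) {
    i <- findInterval(pp, cdf, all.inside = TRUE)
    c0 <- cdf[i]; c1 <- cdf[i + 1]
    if (c1 <= c0) g[i] else g[i] + (pp - c0) / (c1 - c0) * (g[i + 1] - g[i])
  }, numeric(1))
}

#' Rescale a density's axis onto the normalized interval [-1, 1]
#'
#' The physical interval between the `lo_q` and `hi_q` quantiles of `pdf`
#' becomes \[-1, 1\]; the density is re-tabulated with the Jacobian of the
#' linear map so it still integrates to 1.  Mass outside the quantile
#' bounds (at most `lo_q + 1 - hi_q`) is clipped and renormalized, which is
#' why the defaults keep 99.8% of the mass.
#'
#' @param pdf a [grid_pdf] on a physical axis (`transform` must be NULL).
#' @param lo_q,hi_q quantile bounds defining the physical interval,
#'   `0 <= lo_q < hi_q <= 1`.
#' @param n_grid number of points of the returned normalized grid.
#' @return A [grid_pdf] on \[-1, 1\] carrying the [axis_transform].
#' @export
normalize_axis <- function(pdf, lo_q = 0.001, hi_q = 0.999, n_grid = 512L) {
  stopifnot(inherits(pdf, "grid_pdf"))
  if (!is.null(pdf$transform))
    stopf("normalize_axis: pdf is already on a normalized axis")
  if (!(lo_q >= 0 && lo_q < hi_q && hi_q <= 1))
    stopf("normalize_axis: need 0 <= lo_q < hi_q <= 1")
  qb <- if (lo_q == 0 && hi_q == 1) range(pdf$grid)
        else grid_pdf_quantile(pdf, c(max(lo_q, 1e-12), min(hi_q, 1 - 1e-12)))
  if (lo_q == 0) qb[1] <- min(pdf$grid)
  if (hi_q == 1) qb[2] <- max(pdf$grid)
  if (qb[2] - qb[1] <= 0) stopf("normalize_axis: degenerate support")
  tr <- axis_transform(qb[1], qb[2])
  z <- seq(-1, 1, length.out = n_grid)
  xphys <- to_physical(tr, z)
  dens <- approx(pdf$grid, pdf$density, xout = xphys, yleft = 0, yright = 0)$y
  dens <- dens / transform_jacobian(tr)     # density wrt z = physical * dx/dz
  grid_pdf(z, dens / trapz(z, dens), transform = tr)
}

#' Map a normalized density back to its physical axis
#'
#' Inverse of [normalize_axis]: re-expresses a `grid_pdf` tabulated on
#' \[-1, 1\] on the physical axis recorded in its transform.
#'
#' @param pdf a [grid_pdf] with a non-NULL transform.
#' @return A [grid_pdf] on the physical axis with `transform = NULL`.
#' @export
denormalize_axis <- function(pdf) {
  stopifnot(inherits(pdf, "grid_pdf"))
  if (is.null(pdf$transform))
    stopf("denormalize_axis: pdf has no axis transform")
  x <- to_physical(pdf$transform, pdf$grid)
  dens <- pdf$density * transform_jacobian(pdf$transform)
  grid_pdf(x, dens / trapz(x, dens), transform = NULL)
}

#' Read / write a tabulated density as CSV with a JSON metadata header
#'
#' The on-disk format is a `#` -prefixed JSON header line carrying the axis
#' transform (if any), followed by a two-column CSV `grid,density`.
#'
#' @param pdf a [grid_pdf].
#' @param path file path.
#' @return `write_grid_pdf` returns `path` invisibly; `read_grid_pdf`
#'   returns the [grid_pdf].
#' @export
write_grid_pdf <- function(pdf, path) {
  stopifnot(inherits(pdf, "grid_pdf"))
  meta <- list(format = "perfdens.grid_pdf", version = 1L)
  if (!is.null(pdf$transform))
    meta$transform <- list(physical_lo = pdf$transform$physical_lo,
                           physical_hi = pdf$transform$physical_hi)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA)), con)
  utils::write.csv(data.frame(grid = pdf$grid, density = pdf$density),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_pdf
#' @export
read_grid_pdf <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# "))
    stopf("read_grid_pdf: missing JSON metadata header in %s", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  df <- utils::read.csv(text = lines[-1])
  tr <- if (!is.null(meta$transform))
    axis_transform(meta$transform$physical_lo, meta$transform$physical_hi)
  grid_pdf(df$grid, df$density, transform = tr)
}
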