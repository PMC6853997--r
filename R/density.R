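# Kernel density profiling of normalized cell positions: 1D axis profiles
# (the "density distribution" curves accompanying 2D scatter panels) and
# 2D density maps with a diagonal-bandwidth Gaussian kernel.

silverman_bw <- function(x) 1.06 * stats::sd(x) * length(x)^(-1/5)

#' One-dimensional density profile along DV or ML
#'
#' Gaussian-kernel density estimate of a sample's positions on one axis.
#' The automatic bandwidth is Silverman's rule `1.06 * sd(x) * n^(-1/5)`.
#' The evaluation grid spans `[min(0, min - 3h), max(1, max + 3h)]`: it
#' covers at least the unit interval and extends three bandwidths past the
#' data so the estimate integrates to ~1 (no clipping at 0 is applied).
#'
#' @param sample a [cord_sample()], data.frame with `dv`/`ml`, or numeric
#'   vector of positions.
#' @param axis `"dv"` or `"ml"` (ignored when `sample` is already a
#'   vector).
#' @param bandwidth positive smoothing parameter, or `"auto"` for
#'   Silverman's rule.
#' @param grid_size number of evaluation points.
#' @return an object of class `density_profile`: `axis`, `grid`,
#'   `density`, `bandwidth`, `n_cells`.
#' @export
density_profile <- function(sample, axis = c("dv", "ml"), bandwidth = "auto",
                            grid_size = 256L) {
  axis <- match.arg(axis)
  x <- if (is.numeric(sample)) sample else {
    pos <- if (inherits(sample, "cord_sample")) sample$positions else sample
    pos[[axis]]
  }
  n <- length(x)
  if (n < 2) data_error("density_profile needs at least 2 cells")
  if (stats::sd(x) == 0)
    numeric_error(sprintf("zero variance on the %s axis; density profile undefined",
                          toupper(axis)))
  h <- if (identical(bandwidth, "auto")) silverman_bw(x) else bandwidth
  if (!is_scalar_number(h) || h <= 0) config_error("bandwidth must be positive or \"auto\"")
  lo <- min(0, min(x) - 3 * h)
  hi <- max(1, max(x) + 3 * h)
  d <- stats::density(x, bw = h, kernel = "gaussian", n = grid_size,
                      from = lo, to = hi)
  structure(list(axis = toupper(axis), grid = d$x, density = d$y,
                 bandwidth = h, n_cells = n),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Density profile (%s axis): %d cells, bandwidth %.4g\n",
              x$axis, x$n_cells, x$bandwidth))
  cat(sprintf("  grid [%.3f, %.3f] x %d points; mode at %.3f; integral %.4f\n",
              min(x$grid), max(x$grid), length(x$grid),
              x$grid[which.max(x$density)], trapz(x$grid, x$density)))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = paste(x$axis, "position (fraction)"),
                 ylab = "density", ...)
  invisible(x)
}

#' Two-dimensional density map over (DV, ML)
#'
#' Product (diagonal-bandwidth) Gaussian kernel estimate on a rectangular
#' grid; per-axis bandwidths follow the same Silverman rule as
#' [density_profile()]. Grids cover at least `[0, 1]` on each axis and
#' extend three bandwidths past the data.
#'
#' @inheritParams density_profile
#' @param grid_size points per axis.
#' @return an object of class `density_map`: `dv_grid`, `ml_grid`,
#'   `density` (matrix, rows = DV, cols = ML), `bandwidth` (length 2),
#'   `n_cells`.
#' @export
density_map_2d <- function(sample, grid_size = 128L, bandwidth = "auto") {
  pos <- if (inherits(sample, "cord_sample")) sample$positions else sample
  dv <- pos$dv; ml <- pos$ml
  n <- length(dv)
  if (n < 2) data_error("density_map_2d needs at least 2 cells")
  if (stats::sd(dv) == 0 || stats::sd(ml) == 0)
    numeric_error("zero variance on an axis; 2D density map undefined")
  if (identical(bandwidth, "auto")) {
    h <- c(silverman_bw(dv), silverman_bw(ml))
  } else {
    h <- rep_len(bandwidth, 2)
    if (any(!is.finite(h)) || any(h <= 0))
      config_error("bandwidth must be positive or \"auto\"")
  }
  gx <- seq(min(0, min(dv) - 3 * h[1]), max(1, max(dv) + 3 * h[1]),
            length.out = grid_size)
  gy <- seq(min(0, min(ml) - 3 * h[2]), max(1, max(ml) + 3 * h[2]),
            length.out = grid_size)
  A <- stats::dnorm(outer(gx, dv, "-"), sd = h[1])   # grid x n
  B <- stats::dnorm(outer(gy, ml, "-"), sd = h[2])
  dens <- (A %*% t(B)) / n
  structure(list(dv_grid = gx, ml_grid = gy, density = dens,
                 bandwidth = h, n_cells = n),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  peak <- arrayInd(which.max(x$density), dim(x$density))
  cat(sprintf("2D density map: %d cells, %dx%d grid, bandwidth (%.4g, %.4g)\n",
              x$n_cells, length(x$dv_grid), length(x$ml_grid),
              x$bandwidth[1], x$bandwidth[2]))
  cat(sprintf("  peak at (dv, ml) = (%.3f, %.3f); integral %.4f\n",
              x$dv_grid[peak[1]], x$ml_grid[peak[2]], map_integral(x)))
  invisible(x)
}

#' @export
plot.density_map <- function(x, ...) {
  graphics::image(x$ml_grid, x$dv_grid, t(x$density),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "ML position", ylab = "DV position", ...)
  graphics::contour(x$ml_grid, x$dv_grid, t(x$density), add = TRUE,
                    drawlabels = FALSE, col = "grey30")
  invisible(x)
}

# double trapezoidal integral of a density map
map_integral <- function(map) {
  rowint <- apply(map$density, 1, function(r) trapz(map$ml_grid, r))
  trapz(map$dv_grid, rowint)
}

# marginalize a 2D map over the other axis -> 1D curve on this axis' grid
map_marginal <- function(map, axis = c("dv", "ml")) {
  axis <- match.arg(axis)
  if (axis == "dv") {
    list(grid = map$dv_grid,
         density = apply(map$density, 1, function(r) trapz(map$ml_grid, r)))
  } else {
    list(grid = map$ml_grid,
         density = apply(map$density, 2, function(cl) trapz(map$dv_grid, cl)))
  }
}
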