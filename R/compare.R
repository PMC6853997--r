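# Full two-group distribution comparison: Hotelling test, per-axis 1D
# density profiles, 2D density maps, centroid shift and significance
# verdict, bundled into one machine-readable record.

#' Compare two pooled position distributions
#'
#' Bundles the two-sample Hotelling's T-squared test, both groups' 1D
#' density profiles on each axis, both 2D density maps, the centroid shift
#' and a significance verdict at the configured threshold. An optional
#' permutation p-value provides an assumption-free companion to the F
#' approximation.
#'
#' @param a,b [cord_sample()] objects (or data.frames with `dv`/`ml`).
#'   When both carry population/level labels they are checked for
#'   agreement.
#' @param alpha significance threshold (default 0.05).
#' @param bandwidth,grid_size passed to [density_profile()] and
#'   [density_map_2d()].
#' @param n_perm permutations for [hotelling_permutation_p()]; 0 disables.
#' @param seed seed for the permutation test.
#' @return an object of class `cord_comparison`.
#' @export
compare_distributions <- function(a, b, alpha = 0.05, bandwidth = "auto",
                                  grid_size = 128L, n_perm = 0L, seed = 1L) {
  lab <- function(s, f) if (inherits(s, "cord_sample")) s[[f]] else NA_character_
  for (f in c("population", "axial_level")) {
    la <- lab(a, f); lb <- lab(b, f)
    if (!is.na(la) && !is.na(lb) && la != lb)
      warning(sprintf("comparing samples with different %s: %s vs %s", f, la, lb))
  }
  test <- hotelling_t2(a, b)
  perm_p <- if (n_perm > 0)
    as.numeric(hotelling_permutation_p(a, b, n_perm = n_perm, seed = seed)) else NULL
  profiles <- list()
  for (ax in c("dv", "ml")) {
    profiles[[ax]] <- list(a = density_profile(a, ax, bandwidth, grid_size),
                           b = density_profile(b, ax, bandwidth, grid_size))
  }
  maps <- list(a = density_map_2d(a, grid_size, bandwidth),
               b = density_map_2d(b, grid_size, bandwidth))
  structure(list(
    population = lab(a, "population"), axial_level = lab(a, "axial_level"),
    group_a = lab(a, "group"), group_b = lab(b, "group"),
    test = test, permutation_p = perm_p,
    profiles = profiles, maps = maps,
    centroid_shift = test$centroid_shift,
    alpha = alpha,
    significant = test$p_value <= alpha,
    seed = as.integer(seed), n_perm = as.integer(n_perm)
  ), class = "cord_comparison")
}

#' @export
print.cord_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Distribution comparison: %s, %s level (%s vs %s)\n",
              x$population, x$axial_level, x$group_a, x$group_b))
  print(x$test, digits = digits)
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p = %.*g (%d permutations, seed %d)\n",
                digits, x$permutation_p, x$n_perm, x$seed))
  cat(sprintf("  verdict at alpha = %g: %s\n", x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' @export
summary.cord_comparison <- function(object, ...) {
  t <- object$test
  data.frame(population = object$population, axial_level = object$axial_level,
             group_a = object$group_a, group_b = object$group_b,
             n1 = t$n1, n2 = t$n2, t2 = t$t2, f_stat = t$f_stat,
             df1 = t$df1, df2 = t$df2, p_value = t$p_value,
             permutation_p = object$permutation_p %||% NA_real_,
             shift_dv = object$centroid_shift[1],
             shift_ml = object$centroid_shift[2],
             significant = object$significant)
}

#' Plot a distribution comparison
#'
#' Four panels: the two groups' 2D density maps, and overlaid 1D density
#' curves on each axis (group a in blue, group b in red).
#'
#' @param x a `cord_comparison`.
#' @param ... unused.
#' @export
plot.cord_comparison <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$maps$a, main = paste(x$group_a %||% "group a"))
  plot(x$maps$b, main = paste(x$group_b %||% "group b"))
  for (ax in c("dv", "ml")) {
    pa <- x$profiles[[ax]]$a; pb <- x$profiles[[ax]]$b
    ylim <- range(0, pa$density, pb$density)
    graphics::plot(pa$grid, pa$density, type = "l", col = "blue", ylim = ylim,
                   xlab = paste(toupper(ax), "position"), ylab = "density",
                   main = paste(toupper(ax), "profiles"))
    graphics::lines(pb$grid, pb$density, col = "red")
  }
  invisible(x)
}

#' Convert a comparison (or test) to a plain serializable record
#'
#' Flattens the S3 object into named lists/vectors of base types so the
#' JSON report round-trips losslessly.
#'
#' @param x a `cord_comparison`.
#' @return a plain list.
#' @export
as_report <- function(x) {
  stopifnot(inherits(x, "cord_comparison"))
  t <- x$test
  list(
    population = x$population, axial_level = x$axial_level,
    group_a = x$group_a, group_b = x$group_b,
    test = list(t2 = t$t2, f = t$f_stat, df1 = t$df1, df2 = t$df2,
                p = t$p_value, n1 = t$n1, n2 = t$n2,
                mean_a = as.numeric(t$mean_a), mean_b = as.numeric(t$mean_b),
                pooled_cov = as.numeric(t$pooled_cov),
                shift = as.numeric(x$centroid_shift)),
    permutation = if (!is.null(x$permutation_p))
      list(p = x$permutation_p, n_perm = x$n_perm, seed = x$seed),
    profiles = lapply(x$profiles, function(ab) lapply(ab, function(p)
      list(axis = p$axis, grid = p$grid, density = p$density,
           bandwidth = p$bandwidth, n_cells = p$n_cells))),
    alpha = x$alpha,
    significant = x$significant
  )
}
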