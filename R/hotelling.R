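# Two-sample Hotelling's T-squared comparison of pooled 2D position
# samples, with the classical F approximation and a permutation companion.
#
# For samples X (n1 x p) and Y (n2 x p) with means x1, x2 and pooled
# unbiased covariance S = ((n1-1) S1 + (n2-1) S2) / (n1 + n2 - 2):
#
#   T^2 = n1 n2 / (n1 + n2) * (x1 - x2)' S^{-1} (x1 - x2)
#   F   = T^2 * (n1 + n2 - p - 1) / (p (n1 + n2 - 2))  ~  F(p, n1 + n2 - p - 1)
#
# under multivariate normality with common covariance. Cells pooled across
# sections and embryos are treated as independent observations, mirroring
# the pooled per-level plots this analysis accompanies; results carry a
# pseudoreplication caveat with the contributing section/embryo counts.

as_position_matrix <- function(x) {
  if (inherits(x, "cord_sample")) x <- x$positions
  if (is.data.frame(x)) {
    if (all(c("dv", "ml") %in% names(x))) x <- cbind(dv = x$dv, ml = x$ml)
    else x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    data_error("positions must be a cord_sample, data.frame with dv/ml, or numeric matrix")
  x
}

# minimal statistic; shared by the test, the permutation loop and the
# calibration machinery. Returns list(t2, f, df1, df2, p, ...).
t2_stat <- function(X, Y, cond_limit = 1e12) {
  n1 <- nrow(X); n2 <- nrow(Y); p <- ncol(X)
  m1 <- colMeans(X); m2 <- colMeans(Y)
  S <- ((n1 - 1) * stats::cov(X) + (n2 - 1) * stats::cov(Y)) / (n1 + n2 - 2)
  ev <- if (all(is.finite(S)))
    eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  else -Inf
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_limit)
    numeric_error("pooled covariance is singular or near-singular; the 2D test is not supported by these data")
  d <- m1 - m2
  t2 <- (n1 * n2 / (n1 + n2)) * drop(crossprod(d, solve(S, d)))
  df1 <- p
  df2 <- n1 + n2 - p - 1
  f <- t2 * df2 / (p * (n1 + n2 - 2))
  list(t2 = t2, f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       m1 = m1, m2 = m2, S = S, n1 = n1, n2 = n2)
}

#' Two-sample Hotelling's T-squared test
#'
#' Compares the mean (DV, ML) position of two pooled samples; the
#' two-dimensional generalization of the pooled-variance Student's t-test.
#' Errors rather than pseudo-inverting when the pooled covariance is
#' singular or near-singular (condition number above `cond_limit`), so a
#' test the data cannot support is never silently reported.
#'
#' @param a,b [cord_sample()] objects, data.frames with `dv`/`ml` columns,
#'   or numeric matrices with one row per cell (any common number of
#'   columns; 2 for the DV/ML analysis).
#' @param cond_limit condition-number threshold for declaring the pooled
#'   covariance degenerate.
#' @return an object of class `hotelling_test`: `t2`, `f_stat`, `df1`,
#'   `df2`, `p_value`, `mean_a`, `mean_b`, `centroid_shift`
#'   (`mean_b - mean_a`), `pooled_cov`, `n1`, `n2`.
#' @examples
#' a <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' b <- a + 2
#' hotelling_t2(a, b)  # T^2 = 48, F = 20 on df (2, 5)
#' @export
hotelling_t2 <- function(a, b, cond_limit = 1e12) {
  X <- as_position_matrix(a); Y <- as_position_matrix(b)
  if (ncol(X) != ncol(Y)) data_error("samples have different dimensions")
  p <- ncol(X); n1 <- nrow(X); n2 <- nrow(Y)
  if (n1 < 3 || n2 < 3)
    data_error(sprintf("each group needs at least 3 cells (got %d and %d)", n1, n2))
  if (n1 + n2 < p + 2)
    data_error("combined sample too small for the F approximation (df2 < 1)")
  s <- t2_stat(X, Y, cond_limit)
  structure(list(
    t2 = s$t2, f_stat = s$f, df1 = s$df1, df2 = s$df2, p_value = s$p,
    mean_a = s$m1, mean_b = s$m2, centroid_shift = s$m2 - s$m1,
    pooled_cov = s$S, n1 = n1, n2 = n2,
    n_sections = c(a = if (inherits(a, "cord_sample")) a$n_sections else NA,
                   b = if (inherits(b, "cord_sample")) b$n_sections else NA),
    n_embryos = c(a = if (inherits(a, "cord_sample")) a$n_embryos else NA,
                  b = if (inherits(b, "cord_sample")) b$n_embryos else NA)
  ), class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, digits = 4, ...) {
  cat("Two-sample Hotelling's T-squared test\n")
  cat(sprintf("  T2 = %.*g, F = %.*g on df (%d, %d), p = %.*g\n",
              digits, x$t2, digits, x$f_stat, x$df1, x$df2, digits, x$p_value))
  cat(sprintf("  n = %d vs %d cells; centroid shift (b - a) = (%.*g, %.*g)\n",
              x$n1, x$n2, digits, x$centroid_shift[1], digits, x$centroid_shift[2]))
  if (!all(is.na(x$n_embryos)))
    cat("  note: cells pooled across sections/embryos are treated as independent\n",
        "  observations (pseudoreplication caveat); embryos per group:",
        paste(x$n_embryos, collapse = " vs "), "\n")
  invisible(x)
}

#' Permutation p-value for the Hotelling comparison
#'
#' Assumption-free companion to the F approximation: group labels are
#' permuted over the pooled cells and the add-one estimator
#' `p = (1 + #\{T2_perm >= T2_obs\}) / (1 + n_perm)` is returned, so the
#' p-value is never exactly zero. Deterministic given `seed`.
#'
#' @inheritParams hotelling_t2
#' @param n_perm number of label permutations (>= 99).
#' @param seed integer seed.
#' @return the permutation p-value (scalar), with attributes `t2_obs` and
#'   `n_perm`.
#' @export
hotelling_permutation_p <- function(a, b, n_perm = 999, seed = 1L,
                                    cond_limit = 1e12) {
  if (n_perm < 99) config_error("n_perm must be at least 99")
  X <- as_position_matrix(a); Y <- as_position_matrix(b)
  obs <- hotelling_t2(X, Y, cond_limit)$t2
  Z <- rbind(X, Y)
  n <- nrow(Z); n1 <- nrow(X)
  set.seed(as.integer(seed))
  tol <- 1e-9 * max(1, obs)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    t2p <- t2_stat(Z[idx, , drop = FALSE], Z[-idx, , drop = FALSE], cond_limit)$t2
    if (t2p >= obs - tol) hits <- hits + 1L
  }
  p <- (1 + hits) / (1 + n_perm)
  attr(p, "t2_obs") <- obs
  attr(p, "n_perm") <- n_perm
  p
}
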