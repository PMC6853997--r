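# Shared fixture builders: everything is generated in code at test time.

# small clean sections/cells pair (2 embryos x 2 sections)
tiny_dataset <- function() {
  sections <- data.frame(
    section_id = c("s1", "s2", "s3", "s4"),
    embryo_id = c("e1", "e1", "e2", "e2"),
    group = c("control", "control", "mutant", "mutant"),
    stage = "e12.5",
    axial_level = c("brachial", "thoracic", "brachial", "thoracic"),
    side = c("left", "right", "left", "right"),
    H = c(200, 210, 195, 205), W = c(100, 104, 98, 101),
    unit = "px")
  cells <- data.frame(
    cell_id = paste0("c", 1:8),
    section_id = rep(c("s1", "s2", "s3", "s4"), each = 2),
    population = "dI2",
    markers = "Foxd3;Brn3a",
    D = c(150, 80, 120, 60, 140, 90, 110, 70),
    alpha_deg = c(80, 45, 60, 30, 85, 50, 65, 35))
  list(sections = sections, cells = cells)
}

# bivariate-normal cord_sample
gauss_sample <- function(n, mean = c(0.5, 0.4),
                         cov = matrix(c(0.02, 0.005, 0.005, 0.015), 2, 2),
                         seed = 1, ...) {
  set.seed(seed)
  R <- chol(cov)
  pts <- sweep(matrix(rnorm(2 * n), n, 2) %*% R, 2, mean, "+")
  cord_sample(data.frame(dv = pts[, 1], ml = pts[, 2]), ...)
}

# the hand-derived 4+4 worked example: unit square and its translate by 2
worked_example <- function() {
  a <- data.frame(dv = c(0, 1, 0, 1), ml = c(0, 0, 1, 1))
  list(a = cord_sample(a), b = cord_sample(a + 2))
}

# local trapezoidal rule (kept independent of package internals)
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# independent T^2 computation for enumeration oracles (deliberately not
# the package's t2_stat): explicit matrix algebra on 2x2 systems
oracle_t2 <- function(X, Y) {
  n1 <- nrow(X); n2 <- nrow(Y)
  S <- ((n1 - 1) * cov(X) + (n2 - 1) * cov(Y)) / (n1 + n2 - 2)
  d <- colMeans(X) - colMeans(Y)
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det
  (n1 * n2 / (n1 + n2)) * drop(t(d) %*% Sinv %*% d)
}
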