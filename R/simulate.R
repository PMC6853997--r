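# Synthetic-data generator: hemicord geometries, per-population
# Gaussian-mixture cell positions in normalized coordinates (truncated to
# the observable window), marker co-labeling, count tables and ISH-like
# intensity images -- with ground truth retained for recovery and
# calibration studies.
#
# Raw measurements are emitted by the exact inverse of the normalization:
#   D = sqrt((dv*H)^2 + (ml*W)^2),  alpha = atan2(dv*H, ml*W) * 180/pi
# so normalize_position() recovers the sampled (dv, ml) to machine
# precision.

#' Specify one Gaussian cluster of a population mixture
#'
#' @param weight mixture weight in (0, 1]; weights of a population's
#'   clusters must sum to 1.
#' @param mean cluster center `c(dv, ml)` in `[0, 1]^2`.
#' @param cov 2x2 symmetric positive-definite covariance.
#' @return a `cluster_spec` list.
#' @export
cluster_spec <- function(weight, mean, cov) {
  if (!is_scalar_number(weight) || weight <= 0 || weight > 1)
    config_error("cluster weight must lie in (0, 1]")
  mean <- as.numeric(mean)
  if (length(mean) != 2 || any(mean < 0) || any(mean > 1))
    config_error("cluster mean must be a (dv, ml) point in [0, 1]^2")
  cov <- matrix(as.numeric(cov), 2, 2)
  if (max(abs(cov - t(cov))) > 1e-12 || any(eigen(cov, symmetric = TRUE,
                                                  only.values = TRUE)$values <= 0))
    config_error("cluster covariance must be symmetric positive-definite")
  structure(list(weight = weight, mean = mean, cov = cov),
            class = "cluster_spec")
}

#' Assemble the ground truth of a synthetic study
#'
#' Defines everything the generator needs: per-population cluster
#' mixtures, marker panels with co-label probabilities, the log-normal
#' section-geometry distributions (log-normal guarantees positive H and
#' W), the Poisson mean of cells per section, and the intensity-image
#' model. Fully serializable; `(truth, seed)` regenerates a dataset
#' bit-identically.
#'
#' @param populations named list; each element a list with `clusters`
#'   (list of [cluster_spec()]), `markers` (character vector carried by
#'   every cell of the population), optional `colabel` (named list of
#'   additional-marker probabilities) and optional `cells_per_section`
#'   overriding the global Poisson mean.
#' @param geometry list with `H` and `W`, each `c(meanlog, sdlog)` of a
#'   log-normal in pixels.
#' @param cells_per_section global Poisson mean of cells per section and
#'   population.
#' @param intensity list `background`, `signal`, `noise_sd` (arbitrary
#'   units) for [simulate_intensity_image()].
#' @param unit declared length unit of the geometry (validated, never used
#'   numerically: the normalized coordinates are unit-free).
#' @return an object of class `cord_truth`.
#' @export
synthetic_truth <- function(populations,
                            geometry = list(H = c(meanlog = log(200), sdlog = 0.08),
                                            W = c(meanlog = log(100), sdlog = 0.08)),
                            cells_per_section = 40,
                            intensity = list(background = 50, signal = 100,
                                             noise_sd = 10),
                            unit = "px") {
  if (!is.list(populations) || is.null(names(populations)) ||
      any(names(populations) == ""))
    config_error("populations must be a named list")
  for (nm in names(populations)) {
    pop <- populations[[nm]]
    if (is.null(pop$clusters) || !length(pop$clusters))
      config_error(paste0("population ", nm, " has no clusters"))
    pop$clusters <- lapply(pop$clusters, function(cl)
      if (inherits(cl, "cluster_spec")) cl else
        cluster_spec(cl$weight, cl$mean, cl$cov))
    w <- sum(vapply(pop$clusters, `[[`, numeric(1), "weight"))
    if (abs(w - 1) > 1e-8)
      config_error(paste0("cluster weights of population ", nm,
                          " must sum to 1 (got ", signif(w, 6), ")"))
    populations[[nm]] <- pop
  }
  for (par in c("H", "W"))
    if (length(geometry[[par]]) != 2 || geometry[[par]][2] <= 0)
      config_error(paste0("geometry$", par, " must be c(meanlog, sdlog > 0)"))
  if (!is_scalar_number(cells_per_section) || cells_per_section <= 0)
    config_error("cells_per_section must be a positive number")
  for (par in c("background", "signal", "noise_sd"))
    if (!is_scalar_number(intensity[[par]]) || intensity[[par]] < 0)
      config_error(paste0("intensity$", par, " must be a non-negative number"))
  structure(list(populations = populations, geometry = geometry,
                 cells_per_section = cells_per_section,
                 intensity = intensity, unit = unit),
            class = "cord_truth")
}

#' Load a named population preset
#'
#' Stylized scenarios encoding qualitative dorsal-interneuron anatomy
#' (e.g. dI2: dorso-medial stream plus ventral cluster; dI5: medial major
#' plus lateral minor cluster), stored as an editable YAML file shipped
#' with the package. They are plausibility presets for method validation,
#' not reconstructions of any measured dataset.
#'
#' @param name one of the preset names (`"dI2"`, `"dI3"`, `"dI5"`,
#'   `"dI6"`), or `NULL` to list available names.
#' @param file optional path to a presets YAML with the same layout.
#' @return a [synthetic_truth()] object (or preset names if `name` is
#'   `NULL`).
#' @export
cord_preset <- function(name = NULL, file = NULL) {
  file <- file %||% system.file("extdata", "presets.yaml", package = "cordmapper")
  spec <- yaml::read_yaml(file)
  if (is.null(name)) return(names(spec$presets))
  if (!name %in% names(spec$presets))
    config_error(paste0("unknown preset '", name, "'; available: ",
                        paste(names(spec$presets), collapse = ", ")))
  p <- spec$presets[[name]]
  pops <- lapply(p$populations, function(pop) {
    list(markers = unlist(pop$markers),
         colabel = pop$colabel,
         cells_per_section = pop$cells_per_section,
         clusters = lapply(pop$clusters, function(cl)
           cluster_spec(cl$weight, unlist(cl$mean),
                        matrix(unlist(cl$cov), 2, 2, byrow = TRUE))))
  })
  synthetic_truth(pops,
                  geometry = list(H = unlist(spec$geometry$H),
                                  W = unlist(spec$geometry$W)),
                  cells_per_section = spec$cells_per_section %||% 40,
                  intensity = spec$intensity %||%
                    list(background = 50, signal = 100, noise_sd = 10))
}

# sample n points from one truncated cluster (rejection, cap per cell)
sample_cluster <- function(n, cl, bound = 1.05, max_tries = 1000L) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  R <- chol(cl$cov)
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  for (tries in seq_len(max_tries)) {
    need <- n - filled
    if (need == 0) break
    z <- matrix(stats::rnorm(2 * need), need, 2) %*% R
    pts <- sweep(z, 2, cl$mean, "+")
    ok <- pts[, 1] >= 0 & pts[, 1] <= bound & pts[, 2] >= 0 & pts[, 2] <= bound
    k <- sum(ok)
    if (k > 0) {
      out[(filled + 1):(filled + k), ] <- pts[ok, , drop = FALSE]
      filled <- filled + k
    }
  }
  if (filled < n)
    numeric_error("cluster truncation rejected too many draws; check cluster spec")
  out
}

# inverse of the normalization: normalized (dv, ml) + geometry -> (D, alpha)
positions_to_raw <- function(dv, ml, H, W) {
  y <- dv * H; x <- ml * W
  data.frame(D = sqrt(y^2 + x^2), alpha_deg = atan2(y, x) * 180 / pi)
}

#' Simulate a full coordinate study
#'
#' Emulates the study design of `n_embryos` embryos with
#' `sections_per_level` transverse hemisections at each axial level. Per
#' section: geometry drawn from the truth's log-normal laws, a Poisson
#' number of cells per population, each cell's (dv, ml) from the
#' population's truncated Gaussian mixture, raw (D, alpha) by the exact
#' inverse transform, and marker sets from the co-label probabilities. A
#' hierarchical seed stream (embryo -> level -> section) makes every
#' section's draw independent of how many other sections exist, and the
#' whole dataset bit-reproducible from `(truth, seed)`.
#'
#' @param truth a [synthetic_truth()].
#' @param n_embryos number of embryos (>= 1).
#' @param sections_per_level sections per embryo per level (>= 1).
#' @param levels axial levels to simulate.
#' @param group condition label stamped on every section.
#' @param seed integer master seed.
#' @return list with `sections`, `cells`, `counts` data.frames (the same
#'   schemas the analysis functions consume), `positions` (the sampled
#'   normalized coordinates, for recovery tests), and `truth`.
#' @export
simulate_dataset <- function(truth, n_embryos = 3, sections_per_level = 5,
                             levels = c("brachial", "thoracic", "lumbar"),
                             group = "control", seed = 1L) {
  if (!inherits(truth, "cord_truth")) config_error("truth must be a cord_truth")
  if (n_embryos < 1 || sections_per_level < 1)
    config_error("n_embryos and sections_per_level must be >= 1")
  sec_rows <- list(); cell_rows <- list()
  for (e in seq_len(n_embryos)) {
    for (li in seq_along(levels)) {
      for (s in seq_len(sections_per_level)) {
        set.seed(derive_seed(seed, e, li, s))
        H <- stats::rlnorm(1, truth$geometry$H[1], truth$geometry$H[2])
        W <- stats::rlnorm(1, truth$geometry$W[1], truth$geometry$W[2])
        sid <- sprintf("%s_e%d_%s_s%d", group, e, levels[li], s)
        sec_rows[[length(sec_rows) + 1L]] <- data.frame(
          section_id = sid, embryo_id = sprintf("%s_e%d", group, e),
          group = group, stage = "e12.5", axial_level = levels[li],
          side = if (s %% 2 == 0) "left" else "right",
          H = H, W = W, unit = truth$unit)
        for (pn in names(truth$populations)) {
          pop <- truth$populations[[pn]]
          lambda <- pop$cells_per_section %||% truth$cells_per_section
          n <- stats::rpois(1, lambda)
          if (n == 0) next
          w <- vapply(pop$clusters, `[[`, numeric(1), "weight")
          comp <- sample.int(length(w), n, replace = TRUE, prob = w)
          pts <- matrix(NA_real_, n, 2)
          for (k in seq_along(w)) {
            idx <- which(comp == k)
            if (length(idx))
              pts[idx, ] <- sample_cluster(length(idx), pop$clusters[[k]])
          }
          markers <- rep(paste(pop$markers, collapse = ";"), n)
          for (cm in names(pop$colabel %||% list())) {
            hit <- stats::runif(n) < pop$colabel[[cm]]
            markers[hit] <- paste(markers[hit], cm, sep = ";")
          }
          raw <- positions_to_raw(pts[, 1], pts[, 2], H, W)
          cell_rows[[length(cell_rows) + 1L]] <- data.frame(
            cell_id = sprintf("%s_%s_c%d", sid, pn, seq_len(n)),
            section_id = sid, population = pn, markers = markers,
            D = raw$D, alpha_deg = raw$alpha_deg,
            dv_true = pts[, 1], ml_true = pts[, 2])
        }
      }
    }
  }
  sections <- do.call(rbind, sec_rows)
  cells_full <- if (length(cell_rows)) do.call(rbind, cell_rows) else
    data.frame(cell_id = character(), section_id = character(),
               population = character(), markers = character(),
               D = numeric(), alpha_deg = numeric(),
               dv_true = numeric(), ml_true = numeric())
  counts <- tally_counts(cells_full, sections)
  list(sections = sections,
       cells = cells_full[c("cell_id", "section_id", "population", "markers",
                            "D", "alpha_deg")],
       counts = counts,
       positions = cells_full[c("cell_id", "section_id", "population",
                                "dv_true", "ml_true")],
       truth = truth, seed = as.integer(seed))
}

# counts table as the group-by tally of the cells table
tally_counts <- function(cells, sections) {
  base <- expand.grid(section_id = sections$section_id,
                      population = unique(cells$population),
                      stringsAsFactors = FALSE)
  if (nrow(base) == 0)
    return(data.frame(embryo_id = character(), group = character(),
                      axial_level = character(), section_id = character(),
                      population = character(), count = integer()))
  key <- paste(cells$section_id, cells$population, sep = "\r")
  t <- table(key)
  bkey <- paste(base$section_id, base$population, sep = "\r")
  base$count <- as.integer(ifelse(bkey %in% names(t), t[bkey], 0L))
  idx <- match(base$section_id, sections$section_id)
  data.frame(embryo_id = sections$embryo_id[idx], group = sections$group[idx],
             axial_level = sections$axial_level[idx],
             section_id = base$section_id, population = base$population,
             count = base$count)
}

#' Simulate a control/shifted pair of group datasets
#'
#' Group B shares everything with group A except that every cluster mean
#' is translated by `delta = c(ddv, dml)` (models phenotypes where a
#' population migrates, e.g. more ventrally for negative ddv). Translated
#' means must stay inside the observable window `[0, 1.05]^2`.
#'
#' @inheritParams simulate_dataset
#' @param delta length-2 shift `c(ddv, dml)` applied to group B cluster
#'   means.
#' @param groups labels for the two conditions.
#' @return list with combined `sections`, `cells`, `counts`, `positions`
#'   tables (both groups), `delta`, and both truths.
#' @export
shifted_pair <- function(truth, delta, n_embryos = 3, sections_per_level = 5,
                         levels = c("brachial", "thoracic", "lumbar"),
                         groups = c("control", "shifted"), seed = 1L) {
  delta <- as.numeric(delta)
  if (length(delta) != 2 || any(!is.finite(delta)))
    config_error("delta must be a finite (ddv, dml) pair")
  pops_b <- truth$populations
  for (pn in names(pops_b)) {
    pops_b[[pn]]$clusters <- lapply(pops_b[[pn]]$clusters, function(cl) {
      m <- cl$mean + delta
      if (any(m < 0) || any(m > 1.05))
        config_error("translated cluster mean leaves [0, 1.05]^2")
      cl$mean <- m
      cl
    })
  }
  truth_b <- truth; truth_b$populations <- pops_b
  da <- simulate_dataset(truth, n_embryos, sections_per_level, levels,
                         group = groups[1], seed = derive_seed(seed, 1))
  db <- simulate_dataset(truth_b, n_embryos, sections_per_level, levels,
                         group = groups[2], seed = derive_seed(seed, 2))
  list(sections = rbind(da$sections, db$sections),
       cells = rbind(da$cells, db$cells),
       counts = rbind(da$counts, db$counts),
       positions = rbind(da$positions, db$positions),
       delta = delta, truth_a = truth, truth_b = truth_b,
       seed = as.integer(seed))
}

#' Simulate an ISH-like intensity image
#'
#' Pixelwise Gaussian background of level `b` and SD `noise_sd`, plus a
#' rectangular signal region of amplitude `signal * condition_fold`. The
#' signal ROI has the run's fixed area (135 x 100 px = 13,500 px^2 by
#' default) and a valid non-overlapping background ROI of the same size is
#' returned beside it.
#'
#' @param truth a [synthetic_truth()] (its `intensity` block is used).
#' @param condition_fold multiplies the signal amplitude (models e.g. a
#'   ~3-fold up-regulation).
#' @param shape image dimensions `c(rows, cols)`; must fit both ROIs.
#' @param roi_shape signal rectangle dimensions `c(rows, cols)`.
#' @param seed integer seed.
#' @return list with `image` (matrix), `roi`, `background_roi` (0-based
#'   half-open rectangles) and `true_net` (= signal * condition_fold).
#' @export
simulate_intensity_image <- function(truth, condition_fold = 1,
                                     shape = c(200, 260),
                                     roi_shape = c(135, 100), seed = 1L) {
  if (!is_scalar_number(condition_fold) || condition_fold <= 0)
    config_error("condition_fold must be positive")
  m <- truth$intensity
  margin <- 10L
  need <- c(roi_shape[1] + 2 * margin, 2 * roi_shape[2] + 3 * margin)
  if (shape[1] < need[1] || shape[2] < need[2])
    data_error(sprintf("image shape %dx%d too small for two %dx%d ROIs",
                       shape[1], shape[2], roi_shape[1], roi_shape[2]))
  set.seed(as.integer(seed))
  img <- matrix(stats::rnorm(prod(shape), m$background, m$noise_sd),
                shape[1], shape[2])
  roi <- c(margin, margin + roi_shape[1], margin, margin + roi_shape[2])
  bg <- c(margin, margin + roi_shape[1],
          2 * margin + roi_shape[2], 2 * margin + 2 * roi_shape[2])
  amp <- m$signal * condition_fold
  img[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4]] <-
    img[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4]] + amp
  list(image = img, roi = roi, background_roi = bg, true_net = amp)
}

#' Empirical rejection-rate study of the two-group tests
#'
#' Repeatedly simulates two groups and records the rejection rate at the
#' nominal level, with a binomial Monte-Carlo confidence interval.
#' Scenarios: a plain bivariate normal (`scenario = list(mean, cov)`,
#' optionally `delta` for a mean shift in group B) for the position tests,
#' or normal per-unit counts (`scenario = list(mean, sd, delta)`) for
#' `counts_auto`. A full [synthetic_truth()] may be given instead, in
#' which case group positions are drawn from its first population's
#' truncated mixture.
#'
#' @param test `"hotelling_F"`, `"hotelling_perm"` or `"counts_auto"`.
#' @param scenario see Details above; `NULL` uses a default bivariate
#'   normal at (0.5, 0.4).
#' @param n_reps number of replicates (>= 100).
#' @param n_per_group observations per group per replicate.
#' @param seed master seed; each replicate uses a derived stream.
#' @param alpha nominal level.
#' @param n_perm permutations per replicate for `"hotelling_perm"`.
#' @return list of class `cord_calibration`: `rate`, `ci` (95% binomial),
#'   `n_reps`, `test`, `alpha`.
#' @export
calibration_study <- function(test = c("hotelling_F", "hotelling_perm",
                                       "counts_auto"),
                              scenario = NULL, n_reps = 2000, n_per_group = 30,
                              seed = 1L, alpha = 0.05, n_perm = 199L) {
  test <- match.arg(test)
  if (n_reps < 100) config_error("n_reps must be at least 100")
  default_cov <- matrix(c(0.02, 0.005, 0.005, 0.015), 2, 2)
  scenario <- scenario %||% list(mean = c(0.5, 0.4), cov = default_cov)
  delta <- scenario$delta %||% c(0, 0)

  draw_group <- function(n, shift = c(0, 0)) {
    if (inherits(scenario, "cord_truth")) {
      pop <- scenario$populations[[1]]
      w <- vapply(pop$clusters, `[[`, numeric(1), "weight")
      comp <- sample.int(length(w), n, replace = TRUE, prob = w)
      pts <- matrix(NA_real_, n, 2)
      for (k in seq_along(w)) {
        idx <- which(comp == k)
        if (length(idx)) {
          cl <- pop$clusters[[k]]
          cl$mean <- pmin(pmax(cl$mean + shift, 0), 1)
          pts[idx, ] <- sample_cluster(length(idx), cl)
        }
      }
      pts
    } else {
      R <- chol(scenario$cov %||% default_cov)
      sweep(matrix(stats::rnorm(2 * n), n, 2) %*% R, 2,
            (scenario$mean %||% c(0.5, 0.4)) + shift, "+")
    }
  }

  rejections <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    if (test == "counts_auto") {
      mu <- scenario$mean %||% 20; sdv <- scenario$sd %||% 3
      dlt <- if (length(delta) == 1) delta else delta[1]
      a <- stats::rnorm(n_per_group, mu, sdv)
      b <- stats::rnorm(n_per_group, mu + dlt, sdv)
      rejections[r] <- compare_counts(a, b, method = "auto",
                                      threshold = alpha)$significant
    } else {
      X <- draw_group(n_per_group)
      Y <- draw_group(n_per_group, shift = delta[1:2])
      if (test == "hotelling_F") {
        rejections[r] <- t2_stat(X, Y)$p <= alpha
      } else {
        p <- hotelling_permutation_p(X, Y, n_perm = n_perm,
                                     seed = derive_seed(seed, r, 7L))
        rejections[r] <- as.numeric(p) <= alpha
      }
    }
  }
  rate <- mean(rejections)
  se <- sqrt(rate * (1 - rate) / n_reps)
  structure(list(rate = rate, ci = c(max(0, rate - 1.96 * se),
                                     min(1, rate + 1.96 * se)),
                 n_reps = n_reps, n_per_group = n_per_group,
                 test = test, alpha = alpha),
            class = "cord_calibration")
}

#' @export
print.cord_calibration <- function(x, ...) {
  cat(sprintf("Calibration (%s): rejection rate %.4f [%.4f, %.4f] at nominal %g\n",
              x$test, x$rate, x$ci[1], x$ci[2], x$alpha))
  cat(sprintf("  %d replicates, n = %d per group\n", x$n_reps, x$n_per_group))
  invisible(x)
}
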