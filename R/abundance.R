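# Scalar quantifications: marker co-labeling proportions, per-level cell
# counts with mean +/- SEM over embryos, two-group count tests (Student's
# t or Mann-Whitney U), and ROI-based in situ hybridization intensity with
# background subtraction.

parse_markers <- function(m) {
  if (is.list(m)) return(lapply(m, as.character))
  strsplit(as.character(m), ";", fixed = TRUE)
}

#' Marker co-labeling proportions per section
#'
#' For each section, the proportion of reference-population cells that also
#' carry the required markers: numerator = cells whose marker set contains
#' `markers_required` and `markers_reference`; denominator = cells whose
#' marker set contains `markers_reference`. Co-labeling is set logic on
#' per-cell marker annotations. Sections with an empty denominator are
#' reported with proportion `NA` and excluded from means with a warning.
#'
#' @param cells data.frame with `section_id` and `markers`
#'   (semicolon-joined string, or a list column of character vectors).
#' @param markers_required marker(s) whose co-expression is being measured.
#' @param markers_reference marker(s) defining the reference population.
#' @return data.frame with `section_id`, `n_reference`, `n_colabeled`,
#'   `proportion`.
#' @examples
#' cells <- data.frame(section_id = "s1",
#'                     markers = c(rep("Foxd3;Pou2f2", 4), rep("Foxd3", 6)))
#' colabel_counts(cells, "Pou2f2", "Foxd3")  # proportion 0.4
#' @export
colabel_counts <- function(cells, markers_required, markers_reference) {
  if (length(markers_required) == 0 || length(markers_reference) == 0)
    config_error("marker sets must be non-empty")
  sets <- parse_markers(cells$markers)
  has <- function(set, need) all(need %in% set)
  in_ref <- vapply(sets, has, logical(1), need = markers_reference)
  in_num <- vapply(sets, has, logical(1),
                   need = union(markers_required, markers_reference))
  agg <- function(flag) {
    t <- tapply(flag, cells$section_id, sum)
    data.frame(section_id = names(t), n = as.integer(t))
  }
  ref <- agg(in_ref); num <- agg(in_num)
  out <- data.frame(section_id = ref$section_id,
                    n_reference = ref$n,
                    n_colabeled = num$n[match(ref$section_id, num$section_id)])
  out$proportion <- ifelse(out$n_reference > 0,
                           out$n_colabeled / out$n_reference, NA_real_)
  if (any(is.na(out$proportion)))
    warning(sprintf("%d section(s) have no reference cells; proportion undefined there",
                    sum(is.na(out$proportion))))
  out
}

#' Summarize cell counts as mean +/- SEM per group and level
#'
#' In `"embryo"` mode (the default replication unit, matching an n = 3
#' embryos x five sections design) each embryo's sections are averaged
#' first, then the grand mean and SEM = sd/sqrt(n) are computed over
#' embryos. `"section"` mode treats sections directly (power exploration
#' only; it inflates the effective n).
#'
#' @param records data.frame with `embryo_id`, `group`, `axial_level`,
#'   `section_id`, `count` (and optionally `population`).
#' @param unit replication unit, `"embryo"` or `"section"`.
#' @return a data.frame of class `cord_count_summary` with one row per
#'   group x level: `group`, `axial_level`, `mean`, `sem`, `n_units`.
#'   Per-unit values are kept in the `"unit_values"` attribute. A single
#'   contributing unit yields SEM 0 and is flagged in `degenerate`.
#' @export
summarize_counts <- function(records, unit = c("embryo", "section")) {
  unit <- match.arg(unit)
  need <- c("embryo_id", "group", "axial_level", "section_id", "count")
  miss <- setdiff(need, names(records))
  if (length(miss)) data_error(paste0("counts table lacks column(s): ",
                                      paste(miss, collapse = ", ")))
  if (any(records$count < 0) || any(records$count != round(records$count)))
    data_error("counts must be non-negative integers")
  key <- interaction(records$group, records$axial_level, drop = TRUE, sep = "|")
  parts <- split(records, key)
  unit_rows <- list(); sum_rows <- list()
  for (p in parts) {
    vals <- if (unit == "embryo") {
      as.numeric(tapply(p$count, p$embryo_id, mean))
    } else {
      as.numeric(tapply(p$count, p$section_id, sum))
    }
    ids <- if (unit == "embryo") names(tapply(p$count, p$embryo_id, mean))
           else names(tapply(p$count, p$section_id, sum))
    n <- length(vals)
    unit_rows[[length(unit_rows) + 1L]] <-
      data.frame(group = p$group[1], axial_level = p$axial_level[1],
                 unit_id = ids, value = vals)
    sum_rows[[length(sum_rows) + 1L]] <-
      data.frame(group = p$group[1], axial_level = p$axial_level[1],
                 mean = mean(vals),
                 sem = if (n > 1) stats::sd(vals) / sqrt(n) else 0,
                 n_units = n, degenerate = n < 2)
  }
  out <- do.call(rbind, sum_rows)
  attr(out, "unit_values") <- do.call(rbind, unit_rows)
  attr(out, "unit") <- unit
  class(out) <- c("cord_count_summary", "data.frame")
  out
}

#' @export
print.cord_count_summary <- function(x, ...) {
  cat(sprintf("Count summary (unit = %s):\n", attr(x, "unit")))
  print.data.frame(x, row.names = FALSE)
  if (any(x$degenerate))
    cat("note: strata with a single unit report SEM = 0 by convention\n")
  invisible(x)
}

#' Two-group comparison of per-unit counts
#'
#' Implements the standard two-group scalar comparison: pooled-variance
#' Student's t-test or Mann-Whitney U. `method = "auto"` applies a stated
#' pretest cascade: Shapiro-Wilk normality non-significant at 0.05 in both
#' groups AND variance-ratio F test non-significant at 0.05 selects
#' Student's t; otherwise Mann-Whitney U (exact when both n <= 8 and there
#' are no ties, normal approximation with tie correction otherwise). All
#' p-values are two-sided; significance is called at `p <= threshold`.
#'
#' @param a,b numeric vectors of per-unit values (e.g. per-embryo mean
#'   counts).
#' @param method `"auto"`, `"student_t"` or `"mann_whitney"`.
#' @param threshold significance threshold (default 0.05).
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return object of class `cord_count_test`: `test_used`, `statistic`,
#'   `p_value`, `significant`, group means and n's.
#' @examples
#' compare_counts(c(10, 12, 11), c(20, 22, 21), method = "student_t")
#' @export
compare_counts <- function(a, b, method = c("auto", "student_t", "mann_whitney"),
                           threshold = 0.05, welch = FALSE) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (method == "auto") {
    normal_ok <- n1 >= 3 && n2 >= 3 &&
      stats::shapiro.test(a)$p.value > 0.05 &&
      stats::shapiro.test(b)$p.value > 0.05
    var_ok <- normal_ok && stats::var.test(a, b)$p.value > 0.05
    method <- if (normal_ok && var_ok) "student_t" else "mann_whitney"
  }
  if (method == "student_t") {
    if (n1 < 2 || n2 < 2)
      data_error("Student's t needs at least 2 values per group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      numeric_error("all values identical in both groups; t statistic undefined")
    ht <- stats::t.test(a, b, var.equal = !welch)
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    if (n1 < 1 || n2 < 1) data_error("Mann-Whitney needs at least 1 value per group")
    if (length(unique(c(a, b))) == 1L) {
      statistic <- n1 * n2 / 2; p <- 1
    } else {
      exact <- n1 <= 8 && n2 <= 8 && !any(duplicated(c(a, b)))
      ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
      statistic <- unname(ht$statistic); p <- ht$p.value
    }
  }
  structure(list(test_used = method, statistic = statistic, p_value = p,
                 significant = p <= threshold, threshold = threshold,
                 n1 = n1, n2 = n2, mean_a = mean(a), mean_b = mean(b)),
            class = "cord_count_test")
}

#' @export
print.cord_count_test <- function(x, digits = 4, ...) {
  lbl <- c(student_t = "Student's t (pooled variance)",
           mann_whitney = "Mann-Whitney U")[x$test_used]
  cat(sprintf("%s: statistic = %.*g, p = %.*g (%s at p <= %g)\n",
              lbl, digits, x$statistic, digits, x$p_value,
              if (x$significant) "significant" else "not significant",
              x$threshold))
  cat(sprintf("  group means %.4g (n=%d) vs %.4g (n=%d)\n",
              x$mean_a, x$n1, x$mean_b, x$n2))
  invisible(x)
}

# ---- ROI intensity ---------------------------------------------------------

roi_area <- function(roi) (roi[2] - roi[1]) * (roi[4] - roi[3])

check_roi <- function(roi, dim, what) {
  if (length(roi) != 4) config_error(sprintf("%s must be c(row0, row1, col0, col1)", what))
  if (roi[2] <= roi[1] || roi[4] <= roi[3])
    config_error(sprintf("%s is empty (half-open [row0,row1) x [col0,col1))", what))
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > dim[1] || roi[4] > dim[2])
    data_error(sprintf("%s extends outside the image (%d x %d)", what, dim[1], dim[2]))
}

rois_overlap <- function(r1, r2) {
  r1[1] < r2[2] && r2[1] < r1[2] && r1[3] < r2[4] && r2[3] < r1[4]
}

#' Quantify ROI intensity with background subtraction
#'
#' Mean pixel value inside a fixed-area signal rectangle minus the mean of
#' an adjacent background rectangle placed on a region devoid of labeling;
#' the subtraction normalizes for background variation, and all values are
#' arbitrary units. Rectangles are 0-based half-open
#' `[row0, row1) x [col0, col1)` pixel index ranges.
#'
#' @param image numeric matrix (grayscale).
#' @param roi signal rectangle `c(row0, row1, col0, col1)`.
#' @param background_roi background rectangle, same format; must not
#'   overlap the signal ROI.
#' @param expected_area fixed signal-ROI area in px^2 enforced across a run
#'   (default 13500; tolerance one row/column of rounding). `NULL` disables
#'   the check.
#' @return object of class `intensity_measurement`: `roi_mean`,
#'   `background_mean`, `net = roi_mean - background_mean`, `roi_area_px`.
#' @export
intensity_quantify <- function(image, roi, background_roi,
                               expected_area = 13500) {
  if (!is.matrix(image) || !is.numeric(image))
    data_error("image must be a numeric matrix")
  check_roi(roi, dim(image), "signal ROI")
  check_roi(background_roi, dim(image), "background ROI")
  if (rois_overlap(roi, background_roi))
    config_error("background ROI overlaps the signal ROI")
  area <- roi_area(roi)
  if (!is.null(expected_area)) {
    tol <- max(roi[2] - roi[1], roi[4] - roi[3])
    if (abs(area - expected_area) > tol)
      config_error(sprintf(
        "signal ROI area %d px^2 differs from the configured fixed area %d px^2",
        area, expected_area))
  }
  sub <- function(r) image[(r[1] + 1):r[2], (r[3] + 1):r[4], drop = FALSE]
  roi_mean <- mean(sub(roi))
  bg_mean <- mean(sub(background_roi))
  structure(list(roi_mean = roi_mean, background_mean = bg_mean,
                 net = roi_mean - bg_mean, roi_area_px = as.integer(area)),
            class = "intensity_measurement")
}

#' @export
print.intensity_measurement <- function(x, digits = 5, ...) {
  cat(sprintf("ROI intensity: signal %.*g - background %.*g = net %.*g a.u. (area %d px^2)\n",
              digits, x$roi_mean, digits, x$background_mean, digits, x$net,
              x$roi_area_px))
  invisible(x)
}

#' Compare background-subtracted intensity between two conditions
#'
#' Per-embryo values are means of net intensity over that embryo's
#' sections; groups are compared with a two-sided pooled-variance Student's
#' t-test on per-embryo means, and the fold change `mean_b / mean_a` is
#' reported (undefined and flagged when `mean_a <= 0`; the test is still
#' computed).
#'
#' @param measurements data.frame with `embryo_id`, `group`, `net` (one
#'   row per section).
#' @param group_a,group_b condition labels; default the first two groups in
#'   sorted order.
#' @param threshold significance threshold.
#' @return object of class `cord_intensity_test` with the t-test fields,
#'   `fold_change` and `fold_change_defined`.
#' @export
compare_intensity <- function(measurements, group_a = NULL, group_b = NULL,
                              threshold = 0.05) {
  need <- c("embryo_id", "group", "net")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) data_error(paste0("measurements lack column(s): ",
                                      paste(miss, collapse = ", ")))
  groups <- sort(unique(as.character(measurements$group)))
  group_a <- group_a %||% groups[1]
  group_b <- group_b %||% setdiff(groups, group_a)[1]
  per_embryo <- function(g) {
    m <- measurements[measurements$group == g, ]
    if (nrow(m) == 0) data_error(paste0("no measurements for group ", g))
    as.numeric(tapply(m$net, m$embryo_id, mean))
  }
  va <- per_embryo(group_a); vb <- per_embryo(group_b)
  if (length(va) < 2 || length(vb) < 2)
    data_error("compare_intensity needs at least 2 embryos per group")
  identical_groups <- stats::sd(c(va, vb)) == 0
  if (identical_groups) {
    statistic <- 0; p <- 1
  } else {
    ht <- stats::t.test(va, vb, var.equal = TRUE)
    statistic <- unname(ht$statistic); p <- ht$p.value
  }
  fc_defined <- mean(va) > 0
  structure(list(group_a = group_a, group_b = group_b,
                 mean_a = mean(va), mean_b = mean(vb),
                 n_a = length(va), n_b = length(vb),
                 statistic = statistic, p_value = p,
                 significant = p <= threshold, threshold = threshold,
                 fold_change = if (fc_defined) mean(vb) / mean(va) else NA_real_,
                 fold_change_defined = fc_defined),
            class = "cord_intensity_test")
}

#' @export
print.cord_intensity_test <- function(x, digits = 4, ...) {
  cat(sprintf("Intensity comparison (%s vs %s), per-embryo Student's t:\n",
              x$group_a, x$group_b))
  cat(sprintf("  means %.4g (n=%d) vs %.4g (n=%d); t = %.*g, p = %.*g (%s)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b, digits, x$statistic,
              digits, x$p_value,
              if (x$significant) "significant" else "not significant"))
  if (x$fold_change_defined)
    cat(sprintf("  fold change (b/a) = %.*g\n", digits, x$fold_change))
  else cat("  fold change undefined (reference mean <= 0)\n")
  invisible(x)
}
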