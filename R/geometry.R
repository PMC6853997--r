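# Geometry normalization: raw polar soma measurements -> dimensionless
# (DV, ML) coordinates, dataset validation, and pooling into population
# samples.
#
# Conventions. Each transverse hemisection carries a measured frame: spinal
# cord height H (ventral-most to dorsal-most point) and hemicord width W
# (central canal to most lateral edge), in one shared unit (px or um). Each
# soma is measured as a distance D from the ventral-most midline point and
# an angle alpha (degrees) between the horizontal medio-lateral axis through
# that point and the ray to the soma. Then
#
#   DV = D * sin(alpha) / H,    ML = |D * cos(alpha)| / W.
#
# The absolute value folds left and right hemisections onto one positive
# hemicord, so alpha in (90, 180] (lateral direction opposite the reference
# direction) maps onto the same coordinates as its mirror 180 - alpha.
# Ratios are unit-free; the package never converts px <-> um.

#' Normalize a polar soma measurement to (DV, ML) coordinates
#'
#' Vectorized core transform. `D`, `alpha_deg`, `H` and `W` are recycled to
#' a common length. Angles are taken in degrees at the interface and
#' converted to radians internally.
#'
#' @param D distance from the ventral-most midline point to the soma center,
#'   same unit as `H` and `W`; must be >= 0.
#' @param alpha_deg angle in degrees in `[0, 180]` between the horizontal
#'   (medio-lateral) axis and the ray to the soma.
#' @param H spinal cord height (> 0).
#' @param W hemicord width (> 0).
#' @param angle_from axis the angle is measured from. The default
#'   `"horizontal"` matches the DV = D sin(alpha)/H convention;
#'   `"vertical"` accommodates re-digitized data measured from the
#'   dorso-ventral axis (alpha_h = 90 - alpha_v).
#' @return a data.frame with columns `dv` and `ml` (dimensionless).
#' @examples
#' normalize_position(200, 90, 200, 100)   # dv = 1, ml = 0
#' normalize_position(5, c(30, 150), 10, 5) # folding: identical rows
#' @export
normalize_position <- function(D, alpha_deg, H, W,
                               angle_from = c("horizontal", "vertical")) {
  angle_from <- match.arg(angle_from)
  if (any(!is.finite(D)) || any(D < 0))
    data_error("normalize_position: D must be finite and >= 0")
  if (any(!is.finite(alpha_deg)) || any(alpha_deg < 0) || any(alpha_deg > 180))
    data_error("normalize_position: alpha_deg must lie in [0, 180]")
  if (any(!is.finite(H)) || any(H <= 0) || any(!is.finite(W)) || any(W <= 0))
    data_error("normalize_position: H and W must be positive")
  a <- if (angle_from == "vertical") (90 - alpha_deg) else alpha_deg
  rad <- a * pi / 180
  data.frame(dv = D * sin(rad) / H, ml = abs(D * cos(rad)) / W)
}

#' Map raw cell measurements onto normalized coordinates
#'
#' Joins a cells table to its sections table and applies
#' [normalize_position()] per cell. All input metadata are carried through;
#' the section's `embryo_id`, `group`, `stage`, `axial_level` and `side`
#' are attached to each cell. Values pushed slightly past 1 by measurement
#' noise are kept (never clamped) and flagged above `flag_threshold` so the
#' downstream statistics see the data as measured.
#'
#' @param cells data.frame with columns `cell_id`, `section_id`,
#'   `population`, `markers` (semicolon-joined), `D`, `alpha_deg`.
#' @param sections data.frame with columns `section_id`, `embryo_id`,
#'   `group`, `stage`, `axial_level`, `side`, `H`, `W` (and optionally
#'   `unit`).
#' @param angle_from see [normalize_position()].
#' @param flag_threshold positions with `dv` or `ml` above this are flagged
#'   as outliers (default 1.05).
#' @return the cells table augmented with section metadata and columns
#'   `dv`, `ml`, `outlier_flag`.
#' @export
normalize_positions <- function(cells, sections,
                                angle_from = c("horizontal", "vertical"),
                                flag_threshold = 1.05) {
  angle_from <- match.arg(angle_from)
  need_c <- c("cell_id", "section_id", "D", "alpha_deg")
  miss <- setdiff(need_c, names(cells))
  if (length(miss)) data_error(paste0("cells table lacks column(s): ",
                                      paste(miss, collapse = ", ")))
  need_s <- c("section_id", "H", "W")
  miss <- setdiff(need_s, names(sections))
  if (length(miss)) data_error(paste0("sections table lacks column(s): ",
                                      paste(miss, collapse = ", ")))
  if (anyDuplicated(sections$section_id))
    data_error("sections table has duplicated section_id values")
  if (any(!is.finite(sections$H)) || any(sections$H <= 0) ||
      any(!is.finite(sections$W)) || any(sections$W <= 0))
    data_error("sections table has non-positive H or W")

  idx <- match(cells$section_id, sections$section_id)
  if (anyNA(idx)) {
    orphans <- unique(cells$section_id[is.na(idx)])
    data_error(paste0("cells reference unknown section_id(s): ",
                      paste(orphans, collapse = ", ")))
  }
  bad <- !is.finite(cells$D) | cells$D < 0 |
    !is.finite(cells$alpha_deg) | cells$alpha_deg < 0 | cells$alpha_deg > 180
  if (any(bad))
    data_error(paste0("invalid D or alpha_deg for cell_id(s): ",
                      paste(cells$cell_id[bad], collapse = ", ")))

  pos <- normalize_position(cells$D, cells$alpha_deg,
                            sections$H[idx], sections$W[idx],
                            angle_from = angle_from)
  meta_cols <- intersect(c("embryo_id", "group", "stage", "axial_level", "side"),
                         names(sections))
  out <- cells
  for (cn in meta_cols) out[[cn]] <- sections[[cn]][idx]
  out$dv <- pos$dv
  out$ml <- pos$ml
  out$outlier_flag <- pos$dv > flag_threshold | pos$ml > flag_threshold
  out
}

#' Validate a coordinate dataset without throwing
#'
#' Every problem is reported, not thrown: orphan cells (no matching
#' section), duplicated identifiers, out-of-range fields, and mixed units.
#' The report is empty iff the dataset is clean.
#'
#' @param sections,cells the two input tables (see
#'   [normalize_positions()]).
#' @return a data.frame of class `cord_validation` with columns `check`,
#'   `id`, `message`; zero rows for a clean dataset.
#' @export
validate_dataset <- function(sections, cells) {
  rows <- list()
  add <- function(check, id, message)
    rows[[length(rows) + 1L]] <<- data.frame(check = check, id = as.character(id),
                                             message = message)

  dup <- unique(sections$section_id[duplicated(sections$section_id)])
  for (d in dup) add("duplicate_section_id", d, "section_id occurs more than once")
  if (!is.null(cells$cell_id)) {
    dupc <- unique(cells$cell_id[duplicated(cells$cell_id)])
    for (d in dupc) add("duplicate_cell_id", d, "cell_id occurs more than once")
  }
  orphan <- !(cells$section_id %in% sections$section_id)
  for (i in which(orphan))
    add("orphan_cell", cells$cell_id[i],
        paste0("references missing section ", cells$section_id[i]))
  badH <- which(!is.finite(sections$H) | sections$H <= 0)
  for (i in badH) add("invalid_H", sections$section_id[i], "H must be > 0")
  badW <- which(!is.finite(sections$W) | sections$W <= 0)
  for (i in badW) add("invalid_W", sections$section_id[i], "W must be > 0")
  if (!is.null(cells$D)) {
    for (i in which(!is.finite(cells$D) | cells$D < 0))
      add("invalid_D", cells$cell_id[i], "D must be >= 0")
  }
  if (!is.null(cells$alpha_deg)) {
    for (i in which(!is.finite(cells$alpha_deg) |
                      cells$alpha_deg < 0 | cells$alpha_deg > 180))
      add("invalid_alpha", cells$cell_id[i], "alpha_deg must lie in [0, 180]")
  }
  if (!is.null(sections$unit)) {
    u <- unique(stats::na.omit(sections$unit))
    if (length(u) > 1)
      add("unit_mismatch", "(dataset)",
          paste0("multiple units declared: ", paste(u, collapse = ", ")))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(check = character(), id = character(), message = character())
  class(out) <- c("cord_validation", "data.frame")
  out
}

#' @export
print.cord_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Dataset validation: clean (no problems found)\n")
  } else {
    cat("Dataset validation:", nrow(x), "problem(s) found\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Construct a pooled population sample
#'
#' A `cord_sample` holds the normalized (DV, ML) positions of one
#' population x group x axial level, pooled across sections and embryos,
#' with the bookkeeping the comparison report needs (cell, section and
#' embryo counts; outlier tally).
#'
#' @param positions data.frame with at least `dv` and `ml`; `cell_id`,
#'   `section_id`, `embryo_id`, `outlier_flag` used when present.
#' @param population,group,axial_level,stage metadata labels.
#' @return an object of class `cord_sample`.
#' @export
cord_sample <- function(positions, population = NA_character_,
                        group = NA_character_, axial_level = NA_character_,
                        stage = NA_character_) {
  if (!all(c("dv", "ml") %in% names(positions)))
    data_error("positions must contain dv and ml columns")
  if (nrow(positions) < 1) data_error("a population sample needs n_cells >= 1")
  structure(list(
    population = population, group = group,
    axial_level = axial_level, stage = stage,
    positions = positions,
    n_cells = nrow(positions),
    n_sections = if (!is.null(positions$section_id))
      length(unique(positions$section_id)) else NA_integer_,
    n_embryos = if (!is.null(positions$embryo_id))
      length(unique(positions$embryo_id)) else NA_integer_,
    n_outliers = if (!is.null(positions$outlier_flag))
      sum(positions$outlier_flag, na.rm = TRUE) else 0L
  ), class = "cord_sample")
}

#' @export
print.cord_sample <- function(x, ...) {
  cat(sprintf("Population sample: %s | group %s | level %s\n",
              x$population, x$group, x$axial_level))
  cat(sprintf("  %d cells from %s sections of %s embryos (%d outlier-flagged)\n",
              x$n_cells, x$n_sections, x$n_embryos, x$n_outliers))
  cat(sprintf("  centroid (dv, ml) = (%.3f, %.3f)\n",
              mean(x$positions$dv), mean(x$positions$ml)))
  invisible(x)
}

#' Pool normalized positions into population samples
#'
#' Partitions a normalized table by the given grouping keys; each input
#' position lands in exactly one sample. Outlier-flagged positions are
#' included (the statistics see the data as measured) but counted.
#'
#' @param positions normalized table from [normalize_positions()].
#' @param by character vector of grouping columns present in `positions`.
#' @return a named list of [cord_sample()] objects, one per distinct key
#'   combination; empty input yields an empty list.
#' @export
pool_samples <- function(positions,
                         by = c("population", "group", "axial_level")) {
  if (nrow(positions) == 0) return(list())
  miss <- setdiff(by, names(positions))
  if (length(miss)) data_error(paste0("grouping key(s) absent from positions: ",
                                      paste(miss, collapse = ", ")))
  key <- interaction(lapply(by, function(k) positions[[k]]),
                     drop = TRUE, sep = "|", lex.order = TRUE)
  parts <- split(positions, key)
  out <- lapply(parts, function(p) {
    grab <- function(k) if (k %in% names(p)) as.character(p[[k]][1]) else NA_character_
    cord_sample(p,
                population  = if ("population" %in% by) grab("population") else grab("population"),
                group       = grab("group"),
                axial_level = grab("axial_level"),
                stage       = grab("stage"))
  })
  out
}
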