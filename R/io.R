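# File contracts: strict delimited-table readers/writers, run
# configuration, image reading, and JSON report serialization.
#
# Dialect: comma-separated, UTF-8, header row, "." decimal, "NA" missing
# token; TSV accepted on read by sniffing the header line. Writers never
# reorder rows.

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

read_table_strict <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) data_error(paste0("file not found: ", path))
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          quote = "\"", comment.char = "", check.names = TRUE,
                          fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    data_error(paste0(path, ": missing required column(s): ",
                      paste(miss, collapse = ", ")))
  for (cn in numeric_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        data_error(sprintf("%s: column '%s' has non-numeric value at data row %d",
                           path, cn, bad[1]))
      df[[cn]] <- conv
    }
  }
  df
}

#' Read a cells table
#'
#' Required columns: `cell_id`, `section_id`, `population`, `markers`
#' (semicolon-joined), `D`, `alpha_deg`. CSV or TSV, header required.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_cells_table <- function(path) {
  read_table_strict(path,
                    required = c("cell_id", "section_id", "population",
                                 "markers", "D", "alpha_deg"),
                    numeric_cols = c("D", "alpha_deg"))
}

#' Read a sections table
#'
#' Required columns: `section_id`, `embryo_id`, `group`, `stage`,
#' `axial_level`, `side`, `H`, `W`; `unit` optional.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sections_table <- function(path) {
  read_table_strict(path,
                    required = c("section_id", "embryo_id", "group", "stage",
                                 "axial_level", "side", "H", "W"),
                    numeric_cols = c("H", "W"))
}

#' Read a per-section counts table
#'
#' Required columns: `embryo_id`, `group`, `axial_level`, `section_id`,
#' `population`, `count`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_counts_table <- function(path) {
  read_table_strict(path,
                    required = c("embryo_id", "group", "axial_level",
                                 "section_id", "population", "count"),
                    numeric_cols = "count")
}

#' Write a table in the package's CSV dialect
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_cord_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a grayscale intensity image
#'
#' Single-channel TIFF or PNG, 8- or 16-bit; multi-channel images are
#' averaged to one channel with a warning. Values are returned on the
#' file's native scale times `scale` (png/tiff decode to [0, 1]; the
#' default rescales to the original integer range when known).
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param scale multiplier applied to decoded values; `NULL` keeps [0, 1].
#' @return numeric matrix.
#' @export
read_intensity_image <- function(path, scale = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path, as.is = FALSE),
                png = png::readPNG(path),
                data_error(paste0("unsupported image format: .", ext)))
  if (length(dim(img)) == 3) {
    warning("multi-channel image; averaging channels")
    img <- apply(img, c(1, 2), mean)
  }
  if (!is.null(scale)) img <- img * scale
  img
}

#' Write a matrix as a 16-bit grayscale TIFF
#'
#' @param image numeric matrix; rescaled into [0, 1] by `max_value`.
#' @param path output path.
#' @param max_value value mapped to white (default: the matrix maximum).
#' @export
write_intensity_image <- function(image, path, max_value = max(image)) {
  scaled <- pmin(pmax(image / max_value, 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

config_schema <- list(
  cells = "character", sections = "character", counts = "character",
  population = "character", group_a = "character", group_b = "character",
  levels = "character", alpha = "numeric", bandwidth = "ANY",
  grid_size = "numeric", permutations = "numeric", seed = "numeric",
  angle_from = "character", flag_threshold = "numeric",
  count_method = "character", count_unit = "character",
  out_dir = "character", figures = "logical")

#' Read and validate a run configuration
#'
#' YAML (or JSON) mapping validated against the published key schema;
#' unknown keys are rejected so typos never silently change an analysis.
#'
#' @param path config file, or a named list already in memory.
#' @return validated named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) config_error(paste0("config file not found: ", path))
    if (tolower(tools::file_ext(path)) == "json")
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    config_error(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  for (k in c("cells", "sections", "group_a", "group_b"))
    if (is.null(cfg[[k]])) config_error(paste0("config key '", k, "' is required"))
  defaults <- list(alpha = 0.05, bandwidth = "auto", grid_size = 128,
                   permutations = 0, seed = 1, angle_from = "horizontal",
                   flag_threshold = 1.05, count_method = "auto",
                   count_unit = "embryo", figures = FALSE)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  if (!is_scalar_number(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    config_error("alpha must lie in (0, 1)")
  cfg
}

#' Write an analysis report as JSON
#'
#' Numbers are written at full precision so reports round-trip
#' losslessly.
#'
#' @param report a plain list (e.g. from [run_pipeline()] or
#'   [as_report()]).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path report path.
#' @return the report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# ---- pipeline --------------------------------------------------------------

#' Run the full analysis pipeline
#'
#' normalize -> pool -> Hotelling comparison per (population, axial level)
#' -> density profiles -> count statistics. Every stage output lands in
#' the report; the provenance block records the config hash, seed and
#' software version, so (inputs, config, seed) fully determine every
#' number. Outlier and pseudoreplication caveats are collected under
#' `warnings`.
#'
#' @param config path to a YAML/JSON run configuration, or an equivalent
#'   named list (see [read_run_config()]).
#' @param out_dir output directory; created if missing. `NULL` skips
#'   writing and just returns the report.
#' @return the analysis report (invisible when written to disk).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  cells <- read_cells_table(cfg$cells)
  sections <- read_sections_table(cfg$sections)
  report_problems <- validate_dataset(sections, cells)
  if (nrow(report_problems) > 0)
    data_error(paste0("dataset validation failed with ", nrow(report_problems),
                      " problem(s); first: ", report_problems$check[1], " (",
                      report_problems$id[1], ")"))
  norm <- normalize_positions(cells, sections, angle_from = cfg$angle_from,
                              flag_threshold = cfg$flag_threshold)
  keep <- norm$group %in% c(cfg$group_a, cfg$group_b)
  if (!is.null(cfg$population)) keep <- keep & norm$population %in% cfg$population
  if (!is.null(cfg$levels)) keep <- keep & norm$axial_level %in% cfg$levels
  norm_used <- norm[keep, ]
  samples <- pool_samples(norm_used, by = c("population", "group", "axial_level"))

  meta <- unique(data.frame(
    population = vapply(samples, `[[`, character(1), "population"),
    axial_level = vapply(samples, `[[`, character(1), "axial_level")))
  comparisons <- list(); warnings_out <- character()
  if (sum(norm$outlier_flag) > 0)
    warnings_out <- c(warnings_out,
                      sprintf("%d position(s) flagged beyond %.2f (kept, not clamped)",
                              sum(norm$outlier_flag), cfg$flag_threshold))
  find_sample <- function(pop, lvl, grp) {
    for (s in samples)
      if (identical(s$population, pop) && identical(s$axial_level, lvl) &&
          identical(s$group, grp)) return(s)
    NULL
  }
  for (i in seq_len(nrow(meta))) {
    pop <- meta$population[i]; lvl <- meta$axial_level[i]
    sa <- find_sample(pop, lvl, cfg$group_a)
    sb <- find_sample(pop, lvl, cfg$group_b)
    if (is.null(sa) || is.null(sb)) {
      warnings_out <- c(warnings_out,
                        sprintf("stratum %s/%s lacks one group; skipped", pop, lvl))
      next
    }
    if (sa$n_cells < 3 || sb$n_cells < 3) {
      warnings_out <- c(warnings_out,
                        sprintf("stratum %s/%s undersized (n = %d, %d); skipped",
                                pop, lvl, sa$n_cells, sb$n_cells))
      next
    }
    cmp <- compare_distributions(sa, sb, alpha = cfg$alpha,
                                 bandwidth = cfg$bandwidth,
                                 grid_size = as.integer(cfg$grid_size),
                                 n_perm = as.integer(cfg$permutations),
                                 seed = as.integer(cfg$seed))
    rec <- as_report(cmp)
    rec$n_sections <- c(sa$n_sections, sb$n_sections)
    rec$n_embryos <- c(sa$n_embryos, sb$n_embryos)
    comparisons[[paste(pop, lvl, sep = "/")]] <- rec
  }
  warnings_out <- c(warnings_out,
                    "cells pooled across sections/embryos are treated as independent observations (pseudoreplication caveat)")

  counts_block <- NULL
  if (!is.null(cfg$counts)) {
    counts <- read_counts_table(cfg$counts)
    counts_block <- list()
    for (pop in unique(counts$population)) {
      cpop <- counts[counts$population == pop, ]
      summ <- summarize_counts(cpop, unit = cfg$count_unit)
      uv <- attr(summ, "unit_values")
      tests <- list()
      for (lvl in unique(summ$axial_level)) {
        va <- uv$value[uv$group == cfg$group_a & uv$axial_level == lvl]
        vb <- uv$value[uv$group == cfg$group_b & uv$axial_level == lvl]
        if (length(va) < 2 || length(vb) < 2) next
        ct <- compare_counts(va, vb, method = cfg$count_method,
                             threshold = cfg$alpha)
        tests[[lvl]] <- list(test_used = ct$test_used, statistic = ct$statistic,
                             p = ct$p_value, significant = ct$significant,
                             mean_a = ct$mean_a, mean_b = ct$mean_b,
                             n_a = ct$n1, n_b = ct$n2)
      }
      counts_block[[pop]] <- list(
        summary = as.data.frame(summ)[c("group", "axial_level", "mean", "sem",
                                        "n_units")],
        tests = tests)
    }
  }

  cfg_serial <- cfg[order(names(cfg))]
  report <- list(
    provenance = list(
      package = "cordmapper",
      version = as.character(utils::packageVersion("cordmapper")),
      config = cfg_serial,
      config_hash = fnv1a_hash(paste(deparse(cfg_serial), collapse = "")),
      seed = as.integer(cfg$seed),
      inputs = list(cells = cfg$cells, sections = cfg$sections,
                    counts = cfg$counts),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    n_cells_used = nrow(norm_used),
    comparisons = comparisons,
    counts = counts_block,
    warnings = warnings_out)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cord_table(norm, file.path(out_dir, "normalized.csv"))
    write_report(report, file.path(out_dir, "report.json"))
    invisible(report)
  } else report
}
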