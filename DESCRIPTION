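Package: cordmapper
Title: Normalized Mapping and Statistical Comparison of Spinal Interneuron Soma Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative comparison of spinal interneuron soma
    distributions between genotypes or conditions in transverse sections.
    Converts raw polar soma measurements (distance and angle from the
    ventral-most midline point) into dimensionless dorso-ventral and
    medio-lateral coordinates normalized by section height and hemicord
    width, pools cells across sections and embryos, and compares two-group
    2D position distributions with the two-sample Hotelling's T-squared
    test (F approximation plus a permutation companion). Also provides
    axis-wise kernel density profiles and 2D density maps, per-embryo
    cell-count summaries with Student's t or Mann-Whitney U comparisons,
    marker co-labeling proportions, ROI-based in situ hybridization
    intensity quantification with background subtraction, and a
    seed-reproducible synthetic-data generator (truncated Gaussian-mixture
    cell positions, section geometries, counts, and intensity images) with
    retained ground truth for calibration and recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
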