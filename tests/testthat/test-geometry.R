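# Normalization of polar soma measurements into (DV, ML) coordinates,
# dataset validation, and pooling.

test_that("normalize_position reproduces the exact trigonometric cases", {
  cases <- list(
    list(D = 200, a = 90, H = 200, W = 100, dv = 1, ml = 0),
    list(D = 0, a = 37, H = 180, W = 95, dv = 0, ml = 0),
    list(D = 5, a = 30, H = 10, W = 5, dv = 0.25, ml = sqrt(3) / 2),
    # side folding: 150 deg maps like its mirror 30 deg
    list(D = 5, a = 150, H = 10, W = 5, dv = 0.25, ml = sqrt(3) / 2))
  for (cs in cases) {
    p <- normalize_position(cs$D, cs$a, cs$H, cs$W)
    expect_equal(p$dv, cs$dv, tolerance = 1e-12)
    expect_equal(p$ml, cs$ml, tolerance = 1e-12)
  }
})

test_that("normalization is scale invariant and folds sides symmetrically", {
  set.seed(11)
  for (i in 1:50) {
    D <- runif(1, 0, 300); a <- runif(1, 0, 180)
    H <- runif(1, 100, 300); W <- runif(1, 50, 150)
    k <- runif(1, 0.01, 50)
    p1 <- normalize_position(D, a, H, W)
    p2 <- normalize_position(k * D, a, k * H, k * W)
    expect_equal(p1$dv, p2$dv, tolerance = 1e-12)
    expect_equal(p1$ml, p2$ml, tolerance = 1e-12)
    pm <- normalize_position(D, 180 - a, H, W)
    expect_equal(p1$dv, pm$dv, tolerance = 1e-12)
    expect_equal(p1$ml, pm$ml, tolerance = 1e-12)
  }
})

test_that("inverse transform from (dv, ml) round-trips through normalization", {
  set.seed(12)
  for (i in 1:100) {
    dv <- runif(1); ml <- runif(1)
    H <- runif(1, 100, 300); W <- runif(1, 50, 150)
    D <- sqrt((dv * H)^2 + (ml * W)^2)
    a <- atan2(dv * H, ml * W) * 180 / pi
    p <- normalize_position(D, a, H, W)
    expect_equal(p$dv, dv, tolerance = 1e-9)
    expect_equal(p$ml, ml, tolerance = 1e-9)
  }
})

test_that("the vertical angle convention mirrors the horizontal one", {
  p_h <- normalize_position(5, 30, 10, 5, angle_from = "horizontal")
  p_v <- normalize_position(5, 60, 10, 5, angle_from = "vertical")
  expect_equal(p_h, p_v, tolerance = 1e-12)
})

test_that("normalize_positions joins metadata and flags outliers without clamping", {
  d <- tiny_dataset()
  d$cells$D[1] <- d$sections$H[1] * 1.10   # dv ~ 1.08 at alpha 90
  d$cells$alpha_deg[1] <- 90
  norm <- normalize_positions(d$cells, d$sections)
  expect_equal(nrow(norm), 8)
  expect_true(all(c("dv", "ml", "outlier_flag", "embryo_id", "group",
                    "axial_level") %in% names(norm)))
  expect_true(norm$outlier_flag[1])
  expect_gt(norm$dv[1], 1.05)              # kept as measured, not clamped
  expect_false(any(norm$outlier_flag[-1]))
  expect_equal(norm$group, d$sections$group[match(norm$section_id,
                                                  d$sections$section_id)])
})

test_that("normalization errors name the offending cells and sections", {
  d <- tiny_dataset()
  bad <- d$cells; bad$section_id[3] <- "missing"
  expect_error(normalize_positions(bad, d$sections), "missing",
               class = "cord_data_error")
  bad <- d$cells; bad$alpha_deg[2] <- 190
  expect_error(normalize_positions(bad, d$sections), "c2",
               class = "cord_data_error")
  bad <- d$cells; bad$D[5] <- -1
  expect_error(normalize_positions(bad, d$sections), "c5",
               class = "cord_data_error")
})

test_that("validate_dataset reports problems without throwing", {
  d <- tiny_dataset()
  expect_equal(nrow(validate_dataset(d$sections, d$cells)), 0)

  cells <- d$cells; cells$section_id[1] <- "nowhere"
  rep1 <- validate_dataset(d$sections, cells)
  expect_equal(rep1$check, "orphan_cell")
  expect_equal(rep1$id, "c1")

  sections <- rbind(d$sections, d$sections[1, ])
  rep2 <- validate_dataset(sections, d$cells)
  expect_true("duplicate_section_id" %in% rep2$check)

  sections <- d$sections; sections$unit[2] <- "um"
  rep3 <- validate_dataset(sections, d$cells)
  expect_true("unit_mismatch" %in% rep3$check)

  cells <- d$cells; cells$D[1] <- -5; cells$alpha_deg[2] <- 200
  rep4 <- validate_dataset(d$sections, cells)
  expect_setequal(rep4$check, c("invalid_D", "invalid_alpha"))
})

test_that("pooling partitions positions and counts sections/embryos", {
  d <- tiny_dataset()
  norm <- normalize_positions(d$cells, d$sections)
  samples <- pool_samples(norm, by = c("population", "group", "axial_level"))
  expect_length(samples, 4)   # 2 groups x 2 levels
  expect_equal(sum(vapply(samples, `[[`, numeric(1), "n_cells")), nrow(norm))
  one <- samples[[grep("control", names(samples))[1]]]
  expect_equal(one$n_sections, 1)
  expect_equal(one$n_embryos, 1)

  # constant key -> identity partition
  all_in_one <- pool_samples(norm, by = "population")
  expect_length(all_in_one, 1)
  expect_equal(all_in_one[[1]]$n_cells, 8)
  expect_equal(all_in_one[[1]]$n_embryos, 2)
  expect_equal(all_in_one[[1]]$n_sections, 4)

  expect_length(pool_samples(norm[0, ]), 0)
})
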