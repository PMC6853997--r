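# Scalar quantifications: co-labeling, count summaries, two-group count
# tests, ROI intensity.

test_that("co-labeling proportions follow set logic per section", {
  cells <- data.frame(
    section_id = rep("s1", 10),
    markers = c(rep("Foxd3;Brn3a;Pou2f2", 4), rep("Foxd3;Brn3a", 6)))
  cc <- colabel_counts(cells, "Pou2f2", "Foxd3")
  expect_equal(cc$n_reference, 10)
  expect_equal(cc$n_colabeled, 4)
  expect_equal(cc$proportion, 0.4)

  # required == reference -> proportion 1
  cc2 <- colabel_counts(cells, "Foxd3", "Foxd3")
  expect_equal(cc2$proportion, 1)

  # empty denominator -> NA with a warning
  cells2 <- rbind(cells, data.frame(section_id = "s2", markers = "Isl1"))
  expect_warning(cc3 <- colabel_counts(cells2, "Pou2f2", "Foxd3"),
                 "no reference cells")
  expect_true(is.na(cc3$proportion[cc3$section_id == "s2"]))
})

test_that("simulated co-label probability is recovered at scale", {
  truth <- cord_preset("dI2")   # dI2 carries Pou2f2 with probability 0.3
  truth$populations$dI2$cells_per_section <- 120
  sim <- simulate_dataset(truth, n_embryos = 3, sections_per_level = 5,
                          levels = c("brachial", "thoracic", "lumbar"),
                          seed = 31)
  cc <- colabel_counts(sim$cells, "Pou2f2", "Foxd3")
  pooled <- sum(cc$n_colabeled) / sum(cc$n_reference)
  expect_gt(sum(cc$n_reference), 5000)
  expect_lt(abs(pooled - 0.3), 0.02)
})

test_that("count summaries compute the embryo-unit mean and SEM", {
  records <- data.frame(
    embryo_id = rep(c("e1", "e2", "e3"), each = 5),
    group = "control", axial_level = "brachial",
    section_id = paste0("s", 1:15),
    count = c(rep(10, 5), rep(11, 5), rep(12, 5)))
  s <- summarize_counts(records, unit = "embryo")
  expect_equal(s$mean, 11)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-10)   # sd(10,11,12) = 1
  expect_equal(s$n_units, 3)
  uv <- attr(s, "unit_values")
  expect_equal(sort(uv$value), c(10, 11, 12))

  # single embryo -> SEM 0 by convention, flagged
  s1 <- summarize_counts(records[records$embryo_id == "e1", ])
  expect_equal(s1$sem, 0)
  expect_true(s1$degenerate)

  # permutation invariance over record order
  s2 <- summarize_counts(records[sample(15), ])
  expect_equal(s2$mean, s$mean)
  expect_equal(s2$sem, s$sem)
})

test_that("Student's t on the worked values matches the hand computation", {
  ct <- compare_counts(c(10, 12, 11), c(20, 22, 21), method = "student_t")
  expect_equal(ct$statistic, -10 / sqrt(2 / 3), tolerance = 1e-10)  # -12.2474
  expect_equal(ct$statistic, -12.247, tolerance = 1e-4)
  expect_equal(ct$p_value, 2.6e-4, tolerance = 0.02)
  expect_true(ct$significant)
  expect_equal(ct$test_used, "student_t")
})

test_that("exact Mann-Whitney matches enumeration on small samples", {
  ct <- compare_counts(c(1, 2, 3), c(4, 5, 6), method = "mann_whitney")
  expect_equal(unname(ct$statistic), 0)          # U = 0
  expect_equal(ct$p_value, 0.1, tolerance = 1e-12)  # 2/20 splits as extreme

  # independent enumeration over all C(6,3) label assignments
  vals <- c(1, 2, 3, 4, 5, 6)
  splits <- combn(6, 3)
  u_obs <- 0
  us <- apply(splits, 2, function(idx) {
    a <- vals[idx]; b <- vals[-idx]
    sum(outer(a, b, ">"))
  })
  p_enum <- mean(pmin(us, 9 - us) <= min(u_obs, 9 - u_obs))
  expect_equal(ct$p_value, p_enum, tolerance = 1e-12)

  # identical groups -> p = 1 and U = n1*n2/2
  ct2 <- compare_counts(c(5, 5, 5), c(5, 5, 5), method = "mann_whitney")
  expect_equal(ct2$p_value, 1)
  expect_false(ct2$significant)
})

test_that("count comparisons are label-symmetric and respect the threshold at equality", {
  a <- c(10, 12, 11, 13); b <- c(14, 16, 15, 17)
  c1 <- compare_counts(a, b, method = "student_t")
  c2 <- compare_counts(b, a, method = "student_t")
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
  expect_equal(c1$statistic, -c2$statistic, tolerance = 1e-12)
  m1 <- compare_counts(a, b, method = "mann_whitney")
  m2 <- compare_counts(b, a, method = "mann_whitney")
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
  expect_equal(unname(m1$statistic + m2$statistic), length(a) * length(b))

  # significance is called at p <= threshold, inclusive
  m3 <- compare_counts(c(1, 2, 3), c(4, 5, 6), method = "mann_whitney",
                       threshold = 0.1)
  expect_equal(m3$p_value, 0.1)
  expect_true(m3$significant)
})

test_that("the auto rule keeps its size under the null", {
  rej <- logical(2000)
  for (r in seq_len(2000)) {
    set.seed(derive_seed(33, r))
    a <- rnorm(3, 20, 3); b <- rnorm(3, 20, 3)
    rej[r] <- compare_counts(a, b, method = "auto")$significant
  }
  expect_lte(mean(rej), 0.07)
})

test_that("degenerate count comparisons behave as specified", {
  expect_error(compare_counts(c(5, 5, 5), c(5, 5, 5), method = "student_t"),
               class = "cord_numeric_error")
  expect_error(compare_counts(5, c(1, 2), method = "student_t"),
               class = "cord_data_error")
})

test_that("ROI intensity subtracts background and ignores constant offsets", {
  img <- matrix(100, 200, 200)
  m <- intensity_quantify(img, c(10, 60, 10, 60), c(10, 60, 70, 120),
                          expected_area = NULL)
  expect_equal(m$net, 0)

  img2 <- matrix(50, 300, 300)
  img2[21:155, 21:120] <- 150            # 135 x 100 signal block
  roi <- c(20, 155, 20, 120)             # 13,500 px^2
  bg <- c(20, 155, 150, 250)
  m2 <- intensity_quantify(img2, roi, bg)
  expect_equal(m2$roi_mean, 150)
  expect_equal(m2$background_mean, 50)
  expect_equal(m2$net, 100)
  expect_equal(m2$roi_area_px, 13500L)

  m3 <- intensity_quantify(img2 + 77.7, roi, bg)
  expect_equal(m3$net, m2$net, tolerance = 1e-9)
})

test_that("ROI geometry and area violations are rejected", {
  img <- matrix(0, 100, 100)
  expect_error(intensity_quantify(img, c(50, 160, 0, 50), c(0, 10, 60, 90),
                                  expected_area = NULL),
               class = "cord_data_error")
  expect_error(intensity_quantify(img, c(0, 50, 0, 50), c(25, 75, 25, 75),
                                  expected_area = NULL),
               class = "cord_config_error")   # overlap
  expect_error(intensity_quantify(img, c(0, 50, 0, 50), c(0, 50, 60, 100),
                                  expected_area = 13500),
               class = "cord_config_error")   # wrong fixed area
})

test_that("intensity comparison recovers net signal and guards fold change", {
  meas <- data.frame(embryo_id = rep(c("e1", "e2", "e3"), each = 5),
                     group = "a",
                     net = rep(c(10, 11, 12), each = 5))
  meas_b <- transform(meas, group = "b", net = net * 3)
  ct <- compare_intensity(rbind(meas, meas_b), "a", "b")
  expect_equal(ct$fold_change, 3, tolerance = 1e-10)
  expect_true(ct$significant)

  same <- rbind(meas, transform(meas, group = "b"))
  ct2 <- compare_intensity(same, "a", "b")
  expect_equal(ct2$p_value, 1, tolerance = 1e-10)
  expect_equal(ct2$fold_change, 1, tolerance = 1e-10)

  zero_a <- transform(meas, net = 0)
  ct3 <- compare_intensity(rbind(zero_a, meas_b), "a", "b")
  expect_false(ct3$fold_change_defined)
  expect_true(is.na(ct3$fold_change))
  expect_true(is.finite(ct3$p_value))   # t still computed
})
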