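# Synthetic generator: reproducibility, inverse-transform identity,
# count consistency, mixture marginals, intensity images, calibration
# plumbing.

test_that("truth construction validates its parameters upfront", {
  expect_error(cluster_spec(0, c(0.5, 0.5), diag(0.01, 2)),
               class = "cord_config_error")
  expect_error(cluster_spec(1, c(1.2, 0.5), diag(0.01, 2)),
               class = "cord_config_error")
  expect_error(cluster_spec(1, c(0.5, 0.5), matrix(c(1, 2, 2, 1), 2)),
               class = "cord_config_error")  # not positive-definite
  expect_error(synthetic_truth(list(p1 = list(clusters = list(
    cluster_spec(0.5, c(0.5, 0.5), diag(0.01, 2)))))),
    class = "cord_config_error")             # weights must sum to 1
})

test_that("identical (truth, seed) regenerate the dataset bit-identically", {
  truth <- cord_preset("dI2")
  s1 <- simulate_dataset(truth, 2, 2, levels = "thoracic", seed = 41)
  s2 <- simulate_dataset(truth, 2, 2, levels = "thoracic", seed = 41)
  expect_identical(s1$sections, s2$sections)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_dataset(truth, 2, 2, levels = "thoracic", seed = 42)
  expect_false(identical(s1$cells, s2$cells) && identical(s1$cells$D, s3$cells$D))
})

test_that("adding sections never perturbs earlier sections' draws", {
  truth <- cord_preset("dI3")
  small <- simulate_dataset(truth, 2, 2, levels = "thoracic", seed = 43)
  big <- simulate_dataset(truth, 2, 4, levels = "thoracic", seed = 43)
  shared <- intersect(small$cells$section_id, big$cells$section_id)
  expect_length(unique(small$cells$section_id), 4)
  expect_length(shared, 4)
  a <- small$cells[small$cells$section_id %in% shared, ]
  b <- big$cells[big$cells$section_id %in% shared, ]
  expect_equal(a$D, b$D)
  expect_equal(a$alpha_deg, b$alpha_deg)
})

test_that("emitted raw measurements invert back to the sampled positions", {
  truth <- cord_preset("dI2")
  sim <- simulate_dataset(truth, 2, 3, seed = 44)
  norm <- normalize_positions(sim$cells, sim$sections)
  expect_equal(norm$dv, sim$positions$dv_true, tolerance = 1e-9)
  expect_equal(norm$ml, sim$positions$ml_true, tolerance = 1e-9)
})

test_that("a near-degenerate cluster collapses onto its mean", {
  truth <- synthetic_truth(list(p = list(
    markers = "M",
    clusters = list(cluster_spec(1, c(0.5, 0.5), diag(1e-12, 2))))))
  sim <- simulate_dataset(truth, 1, 3, levels = "thoracic", seed = 45)
  expect_true(all(abs(sim$positions$dv_true - 0.5) < 1e-3))
  expect_true(all(abs(sim$positions$ml_true - 0.5) < 1e-3))
})

test_that("total cell numbers concentrate around the Poisson expectation", {
  truth <- cord_preset("dI3")   # lambda = 40 per section
  sim <- simulate_dataset(truth, 2, 5, seed = 46)   # 30 sections
  n <- nrow(sim$cells)
  expect_lt(abs(n - 1200), 3 * sqrt(1200))
})

test_that("the counts table is the exact tally of the cells table", {
  truth <- cord_preset("dI5")
  sim <- simulate_dataset(truth, 2, 3, seed = 47)
  expect_equal(sum(sim$counts$count), nrow(sim$cells))
  for (i in sample(nrow(sim$counts), 10)) {
    expect_equal(sim$counts$count[i],
                 sum(sim$cells$section_id == sim$counts$section_id[i] &
                       sim$cells$population == sim$counts$population[i]))
  }
})

test_that("empirical mixture weights match the generating weights at scale", {
  truth <- cord_preset("dI2")
  truth$populations$dI2$cells_per_section <- 250
  sim <- simulate_dataset(truth, 3, 5, levels = c("brachial", "thoracic", "lumbar"),
                          seed = 48)
  expect_gt(nrow(sim$cells), 10000)
  # assign each cell to the nearer cluster mean (well-separated preset)
  m1 <- truth$populations$dI2$clusters[[1]]$mean
  m2 <- truth$populations$dI2$clusters[[2]]$mean
  p <- sim$positions
  d1 <- (p$dv_true - m1[1])^2 + (p$ml_true - m1[2])^2
  d2 <- (p$dv_true - m2[1])^2 + (p$ml_true - m2[2])^2
  w1 <- mean(d1 < d2)
  expect_lt(abs(w1 - 0.6), 0.02)
})

test_that("shifted_pair translates cluster means and validates bounds", {
  truth <- cord_preset("dI3")
  pair <- shifted_pair(truth, c(-0.1, 0), n_embryos = 1, sections_per_level = 3,
                       levels = "thoracic", seed = 49)
  expect_setequal(unique(pair$sections$group), c("control", "shifted"))
  expect_equal(pair$truth_b$populations$dI3$clusters[[1]]$mean,
               truth$populations$dI3$clusters[[1]]$mean + c(-0.1, 0))
  expect_error(shifted_pair(truth, c(0.6, 0)), class = "cord_config_error")
  expect_error(shifted_pair(truth, c(NA, 0)), class = "cord_config_error")
})

test_that("noiseless intensity images yield the exact configured net", {
  truth <- cord_preset("dI2")
  truth$intensity$noise_sd <- 0
  im <- simulate_intensity_image(truth, condition_fold = 2, seed = 50)
  m <- intensity_quantify(im$image, im$roi, im$background_roi)
  expect_equal(m$net, im$true_net)
  expect_equal(m$net, 200)   # signal 100 x fold 2

  im2 <- simulate_intensity_image(truth, condition_fold = 2, seed = 50)
  expect_identical(im$image, im2$image)
  expect_error(simulate_intensity_image(truth, shape = c(50, 50)),
               class = "cord_data_error")
})

test_that("noisy intensity images recover the net within sampling error", {
  truth <- cord_preset("dI2")   # noise_sd = 10, signal = 100
  im <- simulate_intensity_image(truth, condition_fold = 1, seed = 51)
  m <- intensity_quantify(im$image, im$roi, im$background_roi)
  sem <- truth$intensity$noise_sd * sqrt(2 / 13500)
  expect_lt(abs(m$net - 100), 3 * sem)
})

test_that("a small calibration run is deterministic and sized sanely", {
  t0 <- Sys.time()
  cal <- calibration_study("hotelling_F", n_reps = 100, n_per_group = 30,
                           seed = 52)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
  cal2 <- calibration_study("hotelling_F", n_reps = 100, n_per_group = 30,
                            seed = 52)
  expect_identical(cal$rate, cal2$rate)
  expect_gte(cal$rate, 0)
  expect_lte(cal$rate, 1)
  expect_error(calibration_study("hotelling_F", n_reps = 50),
               class = "cord_config_error")
})
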