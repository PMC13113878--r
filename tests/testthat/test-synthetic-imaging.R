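test_that("preset registry reproduces the reported condition means", {
  reg <- preset_registry()
  # concentration series at 2 h
  pcts <- c("7.5:2", "15:2", "30:2", "50:2")
  expect_equal(vapply(reg[pcts], `[[`, 0, "mean_granule_count"),
               c(`7.5:2` = 50, `15:2` = 87, `30:2` = 73, `50:2` = 42))
  expect_equal(vapply(reg[pcts], `[[`, 0, "mean_granule_area"),
               c(`7.5:2` = 1.33, `15:2` = 1.42, `30:2` = 0.82, `50:2` = 0.49))
  # time series at 15%
  expect_equal(sg_preset(15, 1)$mean_granule_count, 82)
  expect_equal(sg_preset(15, 4)$mean_granule_count, 71)
  expect_equal(sg_preset(15, 6)$mean_granule_count, 54)
  expect_equal(sg_preset(15, 1)$mean_granule_area, 1.09)
  expect_equal(sg_preset(15, 4)$mean_granule_area, 1.19)
  expect_equal(sg_preset(15, 6)$mean_granule_area, 1.12)
  # vehicle and the borderline concentration
  expect_equal(sg_preset(0, 2)$mean_granule_count, 0)
  expect_equal(sg_preset(7.5, 2)$formation_probability, 0.6)
  expect_equal(sg_preset(15, 2)$cyto_fold_vs_vehicle, 4)
  # invariants hold for every entry
  for (p in reg) {
    expect_true(p$formation_probability >= 0 && p$formation_probability <= 1)
    if (p$extract_pct == 0) expect_identical(p$mean_granule_count, 0)
  }
  expect_error(sg_preset(99, 2), "unknown condition")
})

test_that("generator is deterministic and validates its inputs", {
  a <- small_sim(11, 30, 2)
  b <- small_sim(11, 30, 2)
  expect_identical(a$roi$channels$G3BP1$pixels, b$roi$channels$G3BP1$pixels)
  expect_identical(a$roi$channels$DAPI$pixels, b$roi$channels$DAPI$pixels)
  expect_identical(a$truth$granules, b$truth$granules)
  c2 <- small_sim(12, 30, 2)
  expect_false(identical(a$roi$channels$G3BP1$pixels, c2$roi$channels$G3BP1$pixels))

  p <- sg_preset(15, 2)
  expect_error(generate_roi(p, seed = 1, width = 0), "positive")
  expect_error(generate_roi(p, seed = 1, pixel_size = -0.1), "positive")
  expect_error(generate_roi(p, seed = 1, width = 64, background_fraction = 1),
               "background_fraction")
})

test_that("vehicle preset renders a diffuse-only marker channel", {
  sim <- small_sim(3, 0, 2, noise = FALSE)
  expect_identical(sim$truth$granule_count, 0L)
  expect_identical(nrow(sim$truth$granules), 0L)
  # exactly two levels: background inside nuclei, background + diffuse outside
  vals <- sort(unique(as.numeric(sim$roi$channels$G3BP1$pixels)))
  expect_length(vals, 2)
  expect_equal(diff(vals), sim$truth$diffuse_cyto_level)
  expect_equal(vals[1], sim$truth$background_level)
})

test_that("noise-free rendering matches the analytic ground-truth integral", {
  for (seed in 1:3) {
    sim <- small_sim(seed, 15, 2, noise = FALSE)
    px_sum <- sum(sim$roi$channels$G3BP1$pixels)
    expect_equal(px_sum, truth_marker_integral(sim$truth),
                 tolerance = 1e-3)
    # with hard disks the identity is in fact exact
    expect_equal(px_sum, truth_marker_integral(sim$truth), tolerance = 1e-12)
  }
})

test_that("granule pixels exceed the diffuse level by exactly the planted amplitude", {
  sim <- small_sim(7, 15, 2, noise = FALSE)
  px <- sim$roi$channels$G3BP1$pixels
  base <- sim$truth$background_level + sim$truth$diffuse_cyto_level
  in_gran <- sim$truth$granule_labels > 0
  expect_true(sim$truth$granule_count > 0)
  expect_true(all(px[in_gran] - base == sim$truth$granule_amplitude))
  # and non-granule cytoplasm sits exactly at the diffuse level
  cyto_only <- sim$truth$nucleus_labels == 0 & !in_gran
  expect_true(all(px[cyto_only] == base))
})

test_that("increasing the cytoplasmic fold strictly increases the noise-free cytoplasmic mean", {
  means <- vapply(c(1, 2, 4), function(f) {
    p <- condition_preset(15, 2, 0, 0, cyto_fold_vs_vehicle = f,
                          formation_probability = 0)
    sim <- generate_roi(p, seed = 9, width = 128, noise = FALSE)
    cyto <- sim$truth$nucleus_labels == 0
    mean(sim$roi$channels$G3BP1$pixels[cyto])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("recorded granule counts and areas have the preset expectations", {
  # count ~ zero-truncated Poisson(87); planted area ~ lognormal(mean 1.42)
  counts <- numeric(100); areas <- numeric(0)
  for (s in 1:100) {
    tr <- generate_roi(sg_preset(15, 2), seed = 1000 + s, width = 512,
                       noise = FALSE)$truth
    counts[s] <- tr$granule_count
    areas <- c(areas, tr$granules$pixel_count * tr$pixel_size^2)
  }
  expect_true(all(counts > 0))
  expect_lt(abs(mean(counts) - 87), 3)          # SE ~ 0.93
  expect_lt(abs(mean(areas) - 1.42) / 1.42, 0.05)
})

test_that("borderline concentration forms granules in about 3 of 5 ROIs", {
  p <- condition_preset(7.5, 2, mean_granule_count = 3,
                        mean_granule_area = 0.1,
                        formation_probability = sg_preset(7.5, 2)$formation_probability)
  formed <- vapply(1:60, function(s) {
    generate_roi(p, seed = 2000 + s, width = 64, noise = FALSE,
                 nucleus_fill_range = c(0.01, 0.02),
                 granule_area_cv = 0)$truth$granule_count > 0
  }, TRUE)
  # binomial(60, 0.6): mean 36, sd 3.8
  expect_gt(mean(formed), 0.6 - 0.2)
  expect_lt(mean(formed), 0.6 + 0.2)
})

test_that("ROI round trip through TIFF plus sidecar is bit-exact", {
  p <- condition_preset(30, 2, mean_granule_count = 15,
                        mean_granule_area = 0.3, cyto_fold_vs_vehicle = 2.5)
  sim <- generate_roi(p, seed = 5, width = 128)
  path <- file.path(withr::local_tempdir(), "roi.tif")
  write_roi(sim$roi, path, truth = sim$truth)
  back <- read_roi(path)
  expect_identical(back$channels$G3BP1$pixels,
                   matrix(as.numeric(sim$roi$channels$G3BP1$pixels), 128, 128))
  expect_equal(back$channels$G3BP1$pixel_size, 0.1)
  expect_equal(back$condition$extract_pct, 30)
  truth_csv <- read.csv(file.path(dirname(path), "roi_truth.csv"))
  expect_equal(sum(truth_csv$type == "granule"), sim$truth$granule_count)
})
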