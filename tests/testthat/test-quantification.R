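test_that("per-granule arithmetic is exact", {
  # one granule of 142 pixels at 0.1 um/pixel has area 1.42 um^2
  lab <- matrix(0L, 32, 32)
  lab[seq_len(142)] <- 1L
  gl <- structure(list(labels = lab, granule_count = 1L, border = FALSE,
                       pixel_size = 0.1, threshold = NA_real_),
                  class = "granule_labels")
  marker <- channel_image(matrix(10, 32, 32), 0.1, "G3BP1")
  cm <- cluster_metrics(marker, gl)
  expect_equal(cm$table$area_um2, 1.42)
  expect_equal(cm$table$mean_intensity, 10)
  expect_equal(cm$table$cumulative_intensity, 1420)
  # cumulative = mean x pixel count, exactly
  expect_identical(cm$table$cumulative_intensity,
                   cm$table$mean_intensity * cm$table$pixel_count)

  # uniform intensity 10 over 50 pixels
  lab2 <- matrix(0L, 16, 16); lab2[1:50] <- 1L
  gl2 <- structure(list(labels = lab2, granule_count = 1L, border = FALSE,
                        pixel_size = 0.1, threshold = NA_real_),
                   class = "granule_labels")
  cm2 <- cluster_metrics(channel_image(matrix(10, 16, 16), 0.1, "G3BP1"), gl2)
  expect_equal(cm2$table$mean_intensity, 10)
  expect_equal(cm2$table$cumulative_intensity, 500)
})

test_that("ROI aggregates equal brute-force pixel-loop recomputation", {
  set.seed(42)
  px <- matrix(sample(0:1000, 64 * 64, TRUE), 64, 64)
  marker <- channel_image(px, 0.1, "G3BP1")
  fix <- disk_fixture(64, rbind(c(1.2, 1.2), c(3.2, 3.2), c(5, 1.5)),
                      radius = 0.45, amplitude = 1, base = 0)
  g <- segment_granules(channel_image(fix$pixels * 2000 + px, 0.1, "G3BP1"),
                        threshold = 1500)
  expect_identical(g$granule_count, 3L)
  cm <- cluster_metrics(marker, g)
  ref <- pixel_loop_sums(px, g$labels)
  expect_equal(cm$table$cumulative_intensity[order(cm$table$id)], ref$sums)
  expect_equal(cm$table$pixel_count, as.integer(ref$counts))
  expect_equal(cm$summary$total_cumulative_sg, sum(ref$sums))
  expect_equal(cm$summary$mean_of_mean_intensity, mean(ref$sums / ref$counts))

  # empty label image gives a summary of zeros
  empty <- segment_granules(marker, threshold = 1e9)
  cm0 <- cluster_metrics(marker, empty)
  expect_identical(nrow(cm0$table), 0L)
  expect_equal(unlist(cm0$summary), c(sg_count = 0, mean_sg_area = 0,
                                      mean_of_mean_intensity = 0,
                                      mean_cumulative_per_sg = 0,
                                      total_cumulative_sg = 0))
})

test_that("nuclear + cytoplasmic cumulative intensity equals the total exactly", {
  for (seed in 1:3) {
    sim <- small_sim(50 + seed, 15, 2, width = 256)
    m <- segment_nuclei(sim$roi$channels$DAPI)
    q <- nucleus_based_metrics(sim$roi$channels$G3BP1, m)
    # integer-valued images: the identity is bit-exact
    expect_identical(q$nuclear_cumulative + q$cytoplasmic_cumulative,
                     q$total_cumulative)
    expect_identical(q$mean_cytoplasmic,
                     q$cytoplasmic_cumulative / q$cytoplasmic_area)
  }
})

test_that("closed forms hold for degenerate nucleus masks", {
  v <- 7
  marker <- channel_image(matrix(v, 20, 20), 0.1, "G3BP1")
  # empty mask: everything is cytoplasm
  empty <- structure(list(labels = matrix(0L, 20, 20), nucleus_count = 0L,
                          nuclear_area = 0, areas = numeric(),
                          pixel_size = 0.1, threshold = NA_real_),
                     class = "nucleus_mask")
  q <- nucleus_based_metrics(marker, empty)
  expect_equal(q$cytoplasmic_cumulative, q$total_cumulative)
  expect_equal(q$mean_cytoplasmic, v / 0.1^2)

  # uniform intensity with nuclear fraction a
  lab <- matrix(0L, 20, 20); lab[1:100] <- 1L  # a = 0.25
  quarter <- structure(list(labels = lab, nucleus_count = 1L,
                            nuclear_area = 1, areas = 1,
                            pixel_size = 0.1, threshold = NA_real_),
                       class = "nucleus_mask")
  q2 <- nucleus_based_metrics(marker, quarter)
  expect_equal(q2$cytoplasmic_cumulative, 0.75 * q2$total_cumulative)
  expect_equal(q2$mean_cytoplasmic, v / 0.1^2)

  # all-nuclear mask is rejected
  full <- structure(list(labels = matrix(1L, 20, 20), nucleus_count = 1L,
                         nuclear_area = 4, areas = 4,
                         pixel_size = 0.1, threshold = NA_real_),
                    class = "nucleus_mask")
  expect_error(nucleus_based_metrics(marker, full), "cytoplasmic area")
})

test_that("noise-free cytoplasmic mean matches the analytic ground truth", {
  sim <- small_sim(60, 15, 2, width = 512, noise = FALSE)
  m <- segment_nuclei(sim$roi$channels$DAPI)
  q <- nucleus_based_metrics(sim$roi$channels$G3BP1, m)
  tr <- sim$truth
  analytic <- (tr$background_level * tr$cyto_pixel_count +
               tr$diffuse_cyto_level * tr$cyto_pixel_count +
               sum(tr$granules$amplitude * tr$granules$pixel_count)) /
    (tr$cyto_pixel_count * tr$pixel_size^2)
  expect_equal(q$mean_cytoplasmic, analytic, tolerance = 0.005)
})

test_that("vehicle normalization turns group means into fold changes", {
  expect_equal(mean(normalize_to_vehicle(c(1, 2, 3), c(1, 2, 3))), 1)
  # reported cytoplasmic p-eIF2a means: 2485 over 700 and 1919 over 724
  expect_equal(normalize_to_vehicle(2485, 700), 3.55, tolerance = 0.001)
  expect_equal(normalize_to_vehicle(1919, 724), 2.6506, tolerance = 0.001)
  expect_error(normalize_to_vehicle(1, numeric()), "empty")
  expect_error(normalize_to_vehicle(1, c(0, 0)), "positive")
})
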