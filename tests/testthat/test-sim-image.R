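test_that("empty scene yields empty masks and zero indices", {
  p <- image_sim_params(n_nuclei = 0, n_myotubes = 0, n_mono_myhc_cells = 0,
                        frac_touching_pairs = 0, seed = 1)
  sc <- simulate_image(p)
  expect_false(any(sc$truth$nucleus_mask))
  expect_false(any(sc$truth$marker_mask))
  tr <- sc$truth$true_indices
  expect_equal(tr$differentiation_index, 0)
  expect_equal(tr$myotube_area_px, 0L)
  expect_true(all(c("no_nuclei", "no_marker_cells") %in% tr$flags))
})

test_that("all-fused scene has true DI = FI = 1", {
  p <- image_sim_params(n_nuclei = 10, n_myotubes = 1,
                        nuclei_per_myotube = 10, n_mono_myhc_cells = 0,
                        frac_touching_pairs = 0, myotube_length_px = 160,
                        seed = 7)
  sc <- simulate_image(p)
  tr <- sc$truth$true_indices
  expect_equal(tr$differentiation_index, 1)
  expect_equal(tr$fusion_index, 1)
  expect_identical(tr$myotube_count, 1L)
})

test_that("worked mixed design enumerates to DI = 0.4, FI = 0.75", {
  p <- image_sim_params(n_nuclei = 20, n_myotubes = 2,
                        nuclei_per_myotube = 3, n_mono_myhc_cells = 2,
                        frac_touching_pairs = 0, seed = 5)
  sc <- simulate_image(p)
  tr <- sc$truth$true_indices
  expect_identical(tr$nuclei_in_marker, 8L)
  expect_equal(tr$differentiation_index, 8 / 20)
  expect_equal(tr$fusion_index, 6 / 8)
})

test_that("stored true indices match an independent enumeration", {
  for (seed in c(1, 13, 27)) {
    sc <- simulate_image(image_sim_params(seed = seed))
    oracle <- oracle_indices_from_truth(sc$truth)
    tr <- sc$truth$true_indices
    expect_identical(tr$nuclei_in_marker, as.integer(oracle$nuclei_in_marker))
    expect_identical(tr$myotube_count, oracle$myotube_count)
    expect_equal(tr$differentiation_index, oracle$differentiation_index)
    expect_equal(tr$fusion_index, oracle$fusion_index)
  }
})

test_that("same seed and params give bit-identical output", {
  p <- image_sim_params(seed = 99)
  a <- simulate_image(p)
  b <- simulate_image(p)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$nucleus_centroids, b$truth$nucleus_centroids)
})

test_that("parameter validation rejects impossible geometry", {
  expect_error(image_sim_params(foreground_level = 10, background_level = 30),
               "foreground_level")
  expect_error(image_sim_params(n_nuclei = 2, n_myotubes = 2,
                                nuclei_per_myotube = 3),
               "n_nuclei")
  expect_error(image_sim_params(image_height_px = 64, image_width_px = 64,
                                myotube_length_px = 120),
               "fit inside")
})

test_that("touching pairs merge under thresholding and carry pair ids", {
  sc <- simulate_image(image_sim_params(seed = 17, noise_sd = 0))
  pairs <- sc$truth$touching_pairs
  expect_gt(nrow(pairs), 0)
  lab <- r_label_components(unclass(sc$truth$nucleus_mask))
  for (pid in unique(pairs$pair_id)) {
    two <- pairs[pairs$pair_id == pid, ]
    px <- cbind(floor(two$row + 0.5) + 1, floor(two$col + 0.5) + 1)
    expect_identical(lab[px][1], lab[px][2])  # one merged blob
  }
})

test_that("rendered channels respect levels and noise clipping", {
  sc0 <- simulate_image(image_sim_params(seed = 3, noise_sd = 0))
  nuc <- sc0$rgb[, , 3]
  expect_setequal(unique(as.vector(nuc)), c(30, 200))
  expect_identical(nuc == 200, unclass(sc0$truth$nucleus_mask))
  scn <- simulate_image(image_sim_params(seed = 3, noise_sd = 25))
  expect_gte(min(scn$rgb), 0)
  expect_lte(max(scn$rgb), 255)
})
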