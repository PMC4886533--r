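test_that("split_channels extracts the stated planes unchanged", {
  arr <- array(0, c(10, 12, 3))
  arr[, , 2] <- 7
  arr[, , 3] <- 3
  ch <- split_channels(arr)
  expect_identical(unclass(ch$nuclei)[1, 1], 3)
  expect_identical(unclass(ch$marker)[1, 1], 7)
  expect_identical(attr(ch$nuclei, "channel_role"), "nuclei")
  # 2-plane stack round-trips the generator's channels exactly
  sc <- simulate_image(image_sim_params(seed = 2))
  ch2 <- split_channels(sc$stack, mapping = c(nuclei = 1L, marker = 2L))
  strip <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  expect_identical(strip(ch2$nuclei), sc$stack[, , 1])
  expect_identical(strip(ch2$marker), sc$stack[, , 2])
})

test_that("split_channels rejects missing planes", {
  expect_error(split_channels(matrix(0, 5, 5)), "channel")
  expect_error(split_channels(array(0, c(5, 5, 2))), "channel")
})

test_that("marker_area on empty, full, and generated masks", {
  expect_identical(marker_area(binary_mask(matrix(FALSE, 10, 10)))$area_px, 0L)
  full <- marker_area(binary_mask(matrix(TRUE, 100, 100)))
  expect_identical(full$area_px, 10000L)
  expect_identical(full$area_fraction, 1)
  sc <- simulate_image(image_sim_params(seed = 4))
  expect_identical(marker_area(sc$truth$marker_mask)$area_px,
                   sum(sc$truth$marker_mask))
})

test_that("marker-positive cell counting by centroid", {
  lab <- matrix(0L, 30, 30)
  lab[3:7, 3:7] <- 1L
  lab[20:24, 20:24] <- 2L
  marker <- matrix(FALSE, 30, 30)
  expect_identical(count_marker_positive_cells(label_map(lab),
                                               binary_mask(marker)), 0L)
  marker[1:10, 1:10] <- TRUE  # covers object 1 centroid only
  expect_identical(count_marker_positive_cells(label_map(lab),
                                               binary_mask(marker)), 1L)
  marker[] <- TRUE
  expect_identical(count_marker_positive_cells(label_map(lab),
                                               binary_mask(marker)), 2L)
  expect_error(count_marker_positive_cells(label_map(lab),
                                           binary_mask(matrix(FALSE, 10, 10))),
               "grids differ")
})

make_scene <- function() {
  # 20 nuclei: two 3-nucleus myotube-like components, two mononucleated
  # marker cells, 12 background nuclei -> DI = 8/20, FI = 6/8
  nuc <- matrix(0L, 120, 120)
  marker <- matrix(FALSE, 120, 120)
  ctr <- list()
  k <- 0
  place_nuc <- function(r, c) {
    k <<- k + 1
    nuc[(r - 1):(r + 1), (c - 1):(c + 1)] <<- k
    ctr[[k]] <<- c(r, c)
  }
  marker[5:15, 5:60] <- TRUE      # component A (3 nuclei)
  for (c in c(12, 30, 48)) place_nuc(10, c)
  marker[30:40, 5:60] <- TRUE     # component B (3 nuclei)
  for (c in c(12, 30, 48)) place_nuc(35, c)
  marker[60:68, 10:18] <- TRUE    # mono cell 1
  place_nuc(64, 14)
  marker[60:68, 30:38] <- TRUE    # mono cell 2
  place_nuc(64, 34)
  for (i in 1:12) place_nuc(85 + 6 * ((i - 1) %% 6), 20 + 30 * ((i - 1) %/% 6))
  list(nuclei = label_map(nuc), marker = binary_mask(marker))
}

test_that("index enumeration on the worked mixed scene", {
  sc <- make_scene()
  for (rule in c("centroid", "overlap")) {
    idx <- compute_indices(sc$nuclei, sc$marker, assignment = rule)
    expect_identical(idx$total_nuclei, 20L)
    expect_identical(idx$nuclei_in_marker, 8L)
    expect_identical(idx$marker_positive_cell_count, 8L)
    expect_identical(idx$myotube_count, 2L)
    expect_equal(idx$differentiation_index, 0.4)
    expect_equal(idx$fusion_index, 0.75)
  }
  # component-as-cell convention: 2 myotubes of 4 occupied components
  idx <- compute_indices(sc$nuclei, sc$marker, fusion_convention = "components")
  expect_equal(idx$fusion_index, 0.5)
})

test_that("degenerate scenes set flags and zero indices", {
  nuc <- matrix(0L, 20, 20)
  nuc[5:7, 5:7] <- 1L
  empty_marker <- binary_mask(matrix(FALSE, 20, 20))
  idx <- compute_indices(label_map(nuc), empty_marker)
  expect_equal(idx$differentiation_index, 0)
  expect_equal(idx$fusion_index, 0)
  expect_true("no_marker_cells" %in% idx$flags)
  idx2 <- compute_indices(label_map(matrix(0L, 20, 20)), empty_marker)
  expect_true("no_nuclei" %in% idx2$flags)
})

test_that("all nuclei in one component gives DI = FI = 1", {
  nuc <- matrix(0L, 40, 40)
  for (i in 1:4) nuc[10 * i - 5, 20] <- i
  nuc[nuc > 0] <- nuc[nuc > 0]  # single-pixel nuclei
  marker <- binary_mask(matrix(TRUE, 40, 40))
  idx <- compute_indices(label_map(nuc), marker)
  expect_equal(idx$differentiation_index, 1)
  expect_equal(idx$fusion_index, 1)
  expect_identical(idx$myotube_count, 1L)
})

test_that("merging mononucleated components cannot decrease fusion index", {
  nuc <- matrix(0L, 60, 60)
  nuc[10, 10] <- 1L
  nuc[10, 40] <- 2L
  nuc[40, 10] <- 3L
  nuc[40, 40] <- 4L
  split_marker <- matrix(FALSE, 60, 60)
  split_marker[8:12, 8:12] <- TRUE
  split_marker[8:12, 38:42] <- TRUE
  split_marker[38:42, 8:12] <- TRUE
  split_marker[38:42, 38:42] <- TRUE
  fi_split <- compute_indices(label_map(nuc),
                              binary_mask(split_marker))$fusion_index
  merged <- split_marker
  merged[8:12, 8:42] <- TRUE  # bridge the two top components
  fi_merged <- compute_indices(label_map(nuc),
                               binary_mask(merged))$fusion_index
  expect_gte(fi_merged, fi_split)
})

test_that("indices always lie in [0,1] with consistent counts", {
  for (seed in 31:35) {
    sc <- simulate_image(image_sim_params(seed = seed))
    res <- quantify_image(sc$rgb)
    expect_gte(res$differentiation_index, 0)
    expect_lte(res$differentiation_index, 1)
    expect_gte(res$fusion_index, 0)
    expect_lte(res$fusion_index, 1)
    expect_lte(res$nuclei_in_marker, res$total_nuclei)
    expect_lte(res$myotube_nuclei, res$nuclei_in_marker)
  }
})
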