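test_that("boundary length counts pixels touching the outside", {
  one <- matrix(FALSE, 5, 5)
  one[3, 3] <- TRUE
  expect_equal(boundary_length(one), 1L)

  sq <- matrix(FALSE, 5, 5)
  sq[2:4, 2:4] <- TRUE
  expect_equal(boundary_length(sq), 8L) # 3x3 square: center is interior

  line <- matrix(FALSE, 3, 7)
  line[2, 2:6] <- TRUE
  expect_equal(boundary_length(line), 5L) # every pixel of a 1x5 line

  # coordinate-set input agrees with the matrix form
  expect_equal(boundary_length(cbind(x = 1:5, y = rep(1, 5))), 5L)
  expect_error(boundary_length(matrix(FALSE, 3, 3)), "empty")

  # random regions agree with the per-pixel reference
  withr::with_seed(5, {
    for (k in 1:20) {
      L <- matrix(runif(100) < 0.4, 10, 10)
      if (!any(L)) next
      expect_equal(boundary_length(L), oracle_boundary(L))
    }
  })
})

test_that("a single peel iteration thresholds, labels and accepts correctly", {
  p <- seg_params()
  blank <- matrix(0L, 20, 20)
  step <- peel_iteration(blank, 40, p)
  expect_equal(nrow(step$accepted), 0L)
  expect_identical(step$remaining, blank)

  blob <- matrix(0L, 20, 20)
  blob[8:12, 8:12] <- 200L
  step <- peel_iteration(blob, 100, p)
  expect_equal(nrow(step$accepted), 1L)
  expect_equal(step$accepted$area_px, 25L)
  expect_equal(step$accepted$accept_threshold, 100L)
  expect_equal(step$accepted$centroid_x, 9) # 0-based mean of cols 8..12
  expect_true(all(step$remaining == 0L))
})

test_that("a fused dumbbell is rejected first, then split into two nuclei", {
  tile <- make_dumbbell_tile(1)
  p <- dumbbell_params()
  working <- tile$tile[, , 3]
  working[!tile$mask] <- 0L
  first <- peel_iteration(working, p$dapi_start_threshold, p)
  expect_equal(nrow(first$accepted), 0L) # joint boundary exceeds perimeter_max
  final <- segment_nuclei(tile, p)
  expect_equal(nrow(final), 2L)
})

test_that("well-separated synthetic nuclei are recovered with accurate centroids", {
  for (k in c(1L, 5L, 40L)) {
    res <- render_slide(single_spot_scene(k, 0, seed = 100 + k))
    tile <- extract_spot_tile(res$image, res$grid[1, ])
    nuc <- segment_nuclei(tile, seg_params())
    expect_equal(nrow(nuc), k)
    truth <- res$truth$nuclei
    for (i in seq_len(nrow(nuc))) {
      d <- sqrt((truth$x - nuc$slide_x[i])^2 + (truth$y - nuc$slide_y[i])^2)
      expect_lt(min(d), 2)
    }
  }
})

test_that("all-dim tiles yield no nuclei and iteration always terminates", {
  dim_tile <- tile_from_channels(matrix(30L, 21, 21))
  expect_equal(nrow(segment_nuclei(dim_tile, seg_params())), 0L)

  # termination bound: saturated tile never accepted (boundary too long)
  sat <- tile_from_channels(matrix(255L, 21, 21))
  p <- seg_params(perimeter_max = 4L)
  expect_equal(nrow(segment_nuclei(sat, p)), 0L)
})

test_that("coarse threshold increments never find more nuclei than fine ones", {
  for (s in 1:5) {
    tile <- make_dumbbell_tile(10 + s)
    fine <- segment_nuclei(tile, seg_params(40, 5, 255, 18, 8))
    coarse <- segment_nuclei(tile, seg_params(40, 50, 255, 18, 8))
    expect_lte(nrow(coarse), nrow(fine))
  }
  # well-separated nuclei are counted identically at any increment
  res <- render_slide(single_spot_scene(12, 0, seed = 31))
  tile <- extract_spot_tile(res$image, res$grid[1, ])
  expect_equal(nrow(segment_nuclei(tile, seg_params(range_increment = 5))),
               nrow(segment_nuclei(tile, seg_params(range_increment = 50))))
})

test_that("accepted pixels are conserved, disjoint, and re-pass acceptance", {
  p <- seg_params()
  for (s in 1:10) {
    tile <- make_random_tile(200 + s)
    nuc <- segment_nuclei(tile, p)
    if (nrow(nuc) == 0L) next
    masked <- tile$tile[, , 3]
    masked[!tile$mask] <- 0L
    # pixel conservation against the start-threshold footprint
    expect_lte(sum(nuc$area_px), sum(masked >= p$dapi_start_threshold))
    # disjointness
    dims <- dim(tile$mask)
    all_idx <- unlist(lapply(nuc$pixels, nucleus_signature, dims = dims))
    expect_equal(anyDuplicated(all_idx), 0L)
    # invariant re-check at the acceptance threshold
    for (i in seq_len(nrow(nuc))) {
      expect_gte(nuc$area_px[i], p$min_area_px)
      expect_lte(nuc$boundary_px[i], p$perimeter_max)
      L <- matrix(FALSE, dims[1], dims[2])
      L[cbind(nuc$pixels[[i]][, 2] + 1L, nuc$pixels[[i]][, 1] + 1L)] <- TRUE
      expect_equal(boundary_length(L), nuc$boundary_px[i])
    }
  }
})

test_that("segmentation matches the brute-force peeling reference", {
  p <- seg_params()
  for (s in 1:25) {
    tile <- make_random_tile(300 + s)
    nuc <- segment_nuclei(tile, p)
    masked <- tile$tile[, , 3]
    masked[!tile$mask] <- 0L
    ref <- oracle_segment(masked, p)
    expect_equal(nrow(nuc), length(ref))
    dims <- dim(tile$mask)
    for (i in seq_len(nrow(nuc))) {
      expect_identical(nucleus_signature(nuc$pixels[[i]], dims),
                       nucleus_signature(ref[[i]]$pixels, dims))
      expect_equal(nuc$accept_threshold[i], ref[[i]]$threshold)
      expect_equal(nuc$boundary_px[i], ref[[i]]$boundary)
    }
  }
})

test_that("the dilation option grows pixel sets without overlap", {
  res <- render_slide(single_spot_scene(8, 0, seed = 77))
  tile <- extract_spot_tile(res$image, res$grid[1, ])
  core <- segment_nuclei(tile, seg_params())
  fat <- segment_nuclei(tile, seg_params(dilate_px = 2L))
  expect_equal(nrow(fat), nrow(core))
  expect_true(all(fat$area_px >= core$area_px))
  dims <- dim(tile$mask)
  all_idx <- unlist(lapply(fat$pixels, nucleus_signature, dims = dims))
  expect_equal(anyDuplicated(all_idx), 0L)
})
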