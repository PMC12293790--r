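test_that("pixel positivity is a closed per-channel range inside the mask", {
  px <- array(0L, c(7, 7, 3))
  px[2, 2, ] <- c(200L, 10L, 10L)   # pure red
  px[3, 3, ] <- c(200L, 10L, 200L)  # magenta: blue exceeds max
  px[4, 4, ] <- c(99L, 0L, 0L)      # just under red min
  img <- slide_image(px, microns_per_pixel = 55 / 8) # r = 4
  tile <- extract_spot_tile(img, list(barcode = "P", center_x = 3,
                                      center_y = 3, diameter_um = 55))
  mp <- marker_params(rgb_min = c(100, 0, 0), rgb_max = c(255, 80, 80))
  mask <- pixel_marker_mask(tile, mp)
  expect_true(mask[2, 2])
  expect_false(mask[3, 3])
  expect_false(mask[4, 4])

  # vacuous thresholds: every in-mask pixel positive, none outside
  vac <- pixel_marker_mask(tile, marker_params(rgb_min = c(0, 0, 0),
                                               rgb_max = c(255, 255, 255)))
  expect_identical(vac, tile$mask)
})

test_that("cell positivity threshold is inclusive at the boundary fraction", {
  mm <- matrix(FALSE, 20, 20)
  mm[1, 1:10] <- TRUE # 10 positive pixels at y = 0
  nuc <- tibble::tibble(
    centroid_x = 5, centroid_y = 2, area_px = 100L, boundary_px = 40L,
    accept_threshold = 40L,
    pixels = list(cbind(x = rep(0:9, 10), y = rep(0:9, each = 10)))
  )
  expect_true(classify_cells(nuc, mm, marker_params())) # 10/100 >= 0.10
  mm[1, 10] <- FALSE
  expect_false(classify_cells(nuc, mm, marker_params())) # 9/100
  expect_false(classify_cells(nuc, matrix(FALSE, 20, 20), marker_params()))
  # absolute-count alternative
  mm[1, 10] <- TRUE
  expect_true(classify_cells(nuc, mm,
    marker_params(cell_positive_mode = "count", cell_positive_pixel_count = 10)))
})

test_that("spot intensity averages the main channel over positive nucleus pixels", {
  blue <- matrix(0, 31, 31)
  blue <- add_gaussian(blue, 15, 15, 2.5, 220)
  red <- matrix(0L, 31, 31)
  red[blue >= 40] <- 120L # constant marker over the whole nucleus
  tile <- tile_from_channels(blue, red = red, radius_px = 15L)
  nuc <- segment_nuclei(tile, seg_params())
  expect_equal(nrow(nuc), 1L)
  mm <- pixel_marker_mask(tile, marker_params())
  expect_equal(spot_intensity(tile, nuc, mm, marker_params()), 120)
  # no positive pixels anywhere -> 0
  expect_equal(spot_intensity(tile, nuc, matrix(FALSE, 31, 31),
                              marker_params()), 0)
})

test_that("red signal without an underlying nucleus is invisible to the spot", {
  blue <- matrix(0, 41, 41)
  blue <- add_gaussian(blue, 14, 14, 2.2, 220)
  red <- matrix(0L, 41, 41)
  red[blue >= 40] <- 150L
  tile_clean <- tile_from_channels(blue, red = red, radius_px = 18L)

  # same scene plus an RBC-like blob: bright red, zero blue, inside the disk
  red_rbc <- red
  d2 <- outer((0:40 - 28)^2, (0:40 - 28)^2, `+`)
  red_rbc[d2 <= 16] <- 200L
  tile_rbc <- tile_from_channels(blue, red = red_rbc, radius_px = 18L)

  m_clean <- quantify_spot(tile_clean, seg_params(), marker_params())
  m_rbc <- quantify_spot(tile_rbc, seg_params(), marker_params())
  expect_equal(m_rbc$n_cells, m_clean$n_cells)
  expect_equal(m_rbc$n_positive_cells, m_clean$n_positive_cells)
  expect_equal(m_rbc$spot_intensity, m_clean$spot_intensity)
  # the looser whole-spot scope does see the confounder
  loose <- marker_params(intensity_scope = "spot")
  expect_gt(quantify_spot(tile_rbc, seg_params(), loose)$spot_intensity,
            quantify_spot(tile_clean, seg_params(), loose)$spot_intensity * 0.99 + 1)
})

test_that("ground-truth positive cells are recovered on a 40-nucleus fixture", {
  res <- render_slide(single_spot_scene(40, 12, seed = 55))
  tile <- extract_spot_tile(res$image, res$grid[1, ])
  m <- quantify_spot(tile, seg_params(), marker_params())
  expect_equal(m$n_cells, 40L)
  expect_equal(m$n_positive_cells, 12L)
  expect_equal(m$pct_positive, 30)
  expect_gt(m$spot_intensity, 60)
})

test_that("blank tiles and extreme fixtures hit the documented bounds", {
  blank <- tile_from_channels(matrix(0L, 15, 15))
  m <- quantify_spot(blank, seg_params(), marker_params())
  expect_equal(unlist(m), c(n_cells = 0, n_positive_cells = 0,
                            pct_positive = 0, spot_intensity = 0))
  res <- render_slide(single_spot_scene(20, 20, seed = 56))
  tile <- extract_spot_tile(res$image, res$grid[1, ])
  m2 <- quantify_spot(tile, seg_params(), marker_params())
  expect_equal(m2$pct_positive, 100)
  expect_lte(m2$spot_intensity, 255)
})

test_that("raising rgb_min never increases positivity measures", {
  res <- render_slide(single_spot_scene(30, 10, seed = 57))
  tile <- extract_spot_tile(res$image, res$grid[1, ])
  mins <- list(c(0, 0, 0), c(60, 0, 0), c(120, 0, 0), c(180, 0, 0),
               c(230, 0, 0), c(255, 0, 0))
  prev_px <- Inf
  prev_cells <- Inf
  for (rm in mins) {
    mp <- marker_params(rgb_min = rm)
    mask <- pixel_marker_mask(tile, mp)
    nuc <- segment_nuclei(tile, seg_params())
    n_pos <- sum(classify_cells(nuc, mask, mp))
    expect_lte(sum(mask), prev_px)
    expect_lte(n_pos, prev_cells)
    prev_px <- sum(mask)
    prev_cells <- n_pos
  }
})

test_that("measurements match the per-pixel brute-force reference exactly", {
  mp <- marker_params(rgb_min = c(80, 0, 0), rgb_max = c(255, 200, 255))
  for (s in 1:8) {
    tile <- withr::with_seed(400 + s, {
      H <- sample(12:32, 1)
      blue <- matrix(0, H, H)
      red <- matrix(sample(0:180, H * H, replace = TRUE), H, H)
      for (k in 1:3) {
        blue <- add_gaussian(blue, runif(1, 2, H - 3), runif(1, 2, H - 3),
                             runif(1, 1.2, 2.5), runif(1, 100, 250))
      }
      tile_from_channels(blue, red = red)
    })
    nuc <- segment_nuclei(tile, seg_params(min_area_px = 5L))
    mm <- pixel_marker_mask(tile, mp)
    got <- tibble::tibble(
      n_cells = nrow(nuc),
      n_positive_cells = sum(classify_cells(nuc, mm, mp)),
      pct_positive = if (nrow(nuc)) 100 * sum(classify_cells(nuc, mm, mp)) / nrow(nuc) else 0,
      spot_intensity = spot_intensity(tile, nuc, mm, mp)
    )
    ref <- oracle_quantify(tile, nuc, mp)
    expect_equal(got$n_cells, ref$n_cells)
    expect_equal(got$n_positive_cells, ref$n_positive_cells)
    expect_equal(got$pct_positive, ref$pct_positive)
    expect_equal(got$spot_intensity, ref$spot_intensity)
  }
})
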