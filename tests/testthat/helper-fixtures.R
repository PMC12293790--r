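# Fixture builders shared across test files. Everything is generated in code;
# no binary data ships with the package.

# a spot_tile around a hand-built RGB stack; the spot disk covers the whole
# (2r+1)-square tile so mask clipping does not interfere unless wanted
tile_from_channels <- function(blue, red = NULL, green = NULL, radius_px = NULL) {
  H <- nrow(blue)
  W <- ncol(blue)
  if (is.null(red)) red <- matrix(0L, H, W)
  if (is.null(green)) green <- matrix(0L, H, W)
  px <- array(0L, c(H, W, 3))
  px[, , 1] <- as.integer(red)
  px[, , 2] <- as.integer(green)
  px[, , 3] <- as.integer(blue)
  cx <- (W - 1) / 2
  cy <- (H - 1) / 2
  if (is.null(radius_px)) radius_px <- ceiling(sqrt(cx^2 + cy^2)) + 1L
  mpp <- 55 / (2 * radius_px)
  img <- slide_image(px, microns_per_pixel = mpp)
  extract_spot_tile(img, list(barcode = "FIX", center_x = cx, center_y = cy,
                              diameter_um = 55))
}

# paint a clipped 2-D Gaussian into a matrix (max composition)
add_gaussian <- function(m, cx, cy, sigma, peak) {
  d2 <- outer((seq_len(nrow(m)) - 1 - cy)^2, (seq_len(ncol(m)) - 1 - cx)^2, `+`)
  pmax(m, round(peak * exp(-d2 / (2 * sigma^2))))
}

# two fused center-bright nuclei: connected at the start threshold (joint
# boundary above perimeter_max), separating into two bright cores as the
# threshold rises
dumbbell_params <- function() {
  seg_params(dapi_start_threshold = 40L, range_increment = 5L,
             dapi_upper_limit = 255L, perimeter_max = 18L, min_area_px = 8L)
}

make_dumbbell_tile <- function(seed) {
  withr::with_seed(seed, {
    sep <- runif(1, 5.0, 6.5)
    peaks <- runif(2, 200, 240)
    ang <- runif(1, 0, pi)
    blue <- matrix(0, 41, 41)
    blue <- add_gaussian(blue, 20 - sep / 2 * cos(ang), 20 - sep / 2 * sin(ang),
                         2.5, peaks[1])
    blue <- add_gaussian(blue, 20 + sep / 2 * cos(ang), 20 + sep / 2 * sin(ang),
                         2.5, peaks[2])
    tile_from_channels(blue, radius_px = 18L)
  })
}

# random small tiles for oracle-equivalence sweeps: a mix of blob scenes and
# unstructured noise
make_random_tile <- function(seed) {
  withr::with_seed(seed, {
    H <- sample(8:32, 1)
    W <- sample(8:32, 1)
    blue <- matrix(0, H, W)
    if (runif(1) < 0.5) {
      for (k in seq_len(sample(1:5, 1))) {
        blue <- add_gaussian(blue, runif(1, 0, W - 1), runif(1, 0, H - 1),
                             runif(1, 1, 3), runif(1, 60, 250))
      }
      noise <- matrix(sample(0:30, H * W, replace = TRUE), H, W)
      blue <- pmax(blue, noise)
    } else {
      blue <- matrix(sample(0:255, H * W, replace = TRUE), H, W)
    }
    tile_from_channels(blue)
  })
}

# single-spot synthetic slide with n nuclei, n_pos of them marker-positive
single_spot_scene <- function(n, n_pos, seed, n_rbc = 0L) {
  spots <- tibble::tibble(center_x = 65, center_y = 65,
                          n_nuclei = as.integer(n),
                          positive_fraction = if (n > 0) n_pos / n else 0)
  scene_spec(spots, width = 131L, height = 131L, n_rbc = n_rbc, seed = seed)
}
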