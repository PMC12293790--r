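#' Synthetic slide specification
#'
#' Describes a slide the generator can render with exact ground truth:
#' circular capture spots populated with center-bright nuclei (clipped 2-D
#' Gaussians in the blue channel — the premise the peeling segmentation
#' relies on), punctate red marker foci inside positive nuclei, and optional
#' nucleus-free red blobs emulating red-blood-cell autofluorescence.
#'
#' Nucleus centers are drawn from a jittered hexagonal lattice inside each
#' spot disk, which guarantees a minimum center separation (so ground-truth
#' counts are recoverable) while filling the spot at tissue-like density.
#'
#' @param spots Tibble with one row per spot: `center_x`, `center_y` (0-based
#'   pixel coordinates), `n_nuclei`, `positive_fraction`.
#' @param width,height Image size in pixels.
#' @param microns_per_pixel Pixel scale (default 0.5, a 20x whole-slide scan).
#' @param diameter_um Spot diameter (default 55).
#' @param nucleus_sigma_px Gaussian sigma of the nuclear profile (default 1.8).
#' @param peak_range DAPI peak intensity range, drawn per nucleus
#'   (default 180--240; boundaries then fall below the default start
#'   threshold of 40, satisfying the center-bright premise).
#' @param hex_spacing_px Lattice spacing for nucleus placement (default 11).
#' @param jitter_px Uniform jitter applied to lattice positions (default 1.5).
#' @param n_foci,focus_radius_px,focus_intensity Punctate marker model for
#'   positive nuclei: number of red foci per nucleus, their disk radius and
#'   red intensity.
#' @param n_rbc,rbc_radius_px,rbc_intensity Red-blood-cell confounders:
#'   red-only blobs (blue forced to 0) placed away from nuclei.
#' @param noise_sd Gaussian background noise SD per channel (default 3).
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(spots, width, height,
                       microns_per_pixel = 0.5, diameter_um = 55,
                       nucleus_sigma_px = 1.8, peak_range = c(180, 240),
                       hex_spacing_px = 11, jitter_px = 1.5,
                       n_foci = 3L, focus_radius_px = 1.2, focus_intensity = 220L,
                       n_rbc = 0L, rbc_radius_px = 4, rbc_intensity = 160L,
                       noise_sd = 3, seed) {
  stopifnot(is.data.frame(spots),
            all(c("center_x", "center_y", "n_nuclei", "positive_fraction") %in%
                  names(spots)),
            width >= 1, height >= 1,
            peak_range[2] <= 255, focus_intensity <= 255, rbc_intensity <= 255,
            !missing(seed))
  structure(
    list(
      spots = tibble::as_tibble(spots),
      width = as.integer(width), height = as.integer(height),
      microns_per_pixel = microns_per_pixel, diameter_um = diameter_um,
      nucleus_sigma_px = nucleus_sigma_px, peak_range = peak_range,
      hex_spacing_px = hex_spacing_px, jitter_px = jitter_px,
      n_foci = as.integer(n_foci), focus_radius_px = focus_radius_px,
      focus_intensity = as.integer(focus_intensity),
      n_rbc = as.integer(n_rbc), rbc_radius_px = rbc_radius_px,
      rbc_intensity = as.integer(rbc_intensity),
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' Standard 20-spot validation scene
#'
#' The reference study conditions for end-to-end tests: 20 spots laid out on
#' a 5 x 4 grid — 8 marker-positive spots (35% positive cells), 10 negative
#' spots, and 2 sparse spots with fewer than 10 nuclei (which the call rule
#' must exclude). Non-sparse spots carry 25--60 nuclei each (mean about 42,
#' the cell density typical of the tissue sections this emulates).
#'
#' @param seed Integer seed.
#' @param n_rbc Number of red-blood-cell confounder blobs (default 0; the
#'   "hard" variant adds them).
#' @return A `scene_spec`.
#' @export
default_scene <- function(seed, n_rbc = 0L) {
  withr::with_seed(seed, {
    r <- spot_radius_px(55, 0.5)
    spacing <- 2L * r + 20L
    centers <- expand.grid(col = 0:4, row = 0:3)
    cx <- spacing %/% 2L + centers$col * spacing
    cy <- spacing %/% 2L + centers$row * spacing
    type <- sample(c(rep("positive", 8), rep("negative", 10), rep("sparse", 2)))
    n_nuclei <- ifelse(type == "sparse", sample(4:7, 20, replace = TRUE),
                       sample(25:60, 20, replace = TRUE))
    spots <- tibble::tibble(
      center_x = cx, center_y = cy,
      n_nuclei = as.integer(n_nuclei),
      positive_fraction = ifelse(type == "positive", 0.35, 0)
    )
    scene_spec(spots, width = 5L * spacing, height = 4L * spacing,
               n_rbc = n_rbc, seed = sample.int(2^31 - 1L, 1L))
  })
}

# hexagonal lattice points inside a disk of radius r around (cx, cy)
hex_positions <- function(cx, cy, r, spacing, margin) {
  rr <- r - margin
  ys <- seq(-rr, rr, by = spacing * sqrt(3) / 2)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    xs <- seq(-rr + off, rr, by = spacing)
    cbind(xs, ys[i])
  }))
  keep <- pts[, 1]^2 + pts[, 2]^2 <= rr^2
  cbind(cx + pts[keep, 1], cy + pts[keep, 2])
}

# paint a radial profile into a channel with pmax composition
paint_gaussian <- function(channel, cx, cy, sigma, peak) {
  H <- nrow(channel); W <- ncol(channel)
  ext <- ceiling(5 * sigma)
  x0 <- max(0L, floor(cx) - ext); x1 <- min(W - 1L, ceiling(cx) + ext)
  y0 <- max(0L, floor(cy) - ext); y1 <- min(H - 1L, ceiling(cy) + ext)
  if (x0 > x1 || y0 > y1) return(channel)
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  patch <- peak * exp(-d2 / (2 * sigma^2))
  i <- (y0 + 1L):(y1 + 1L); j <- (x0 + 1L):(x1 + 1L)
  channel[i, j] <- pmax(channel[i, j], patch)
  channel
}

paint_disk <- function(channel, cx, cy, radius, value) {
  H <- nrow(channel); W <- ncol(channel)
  ext <- ceiling(radius)
  x0 <- max(0L, floor(cx) - ext); x1 <- min(W - 1L, ceiling(cx) + ext)
  y0 <- max(0L, floor(cy) - ext); y1 <- min(H - 1L, ceiling(cy) + ext)
  if (x0 > x1 || y0 > y1) return(channel)
  xs <- x0:x1; ys <- y0:y1
  inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= radius^2
  i <- (y0 + 1L):(y1 + 1L); j <- (x0 + 1L):(x1 + 1L)
  channel[i, j][inside] <- pmax(channel[i, j][inside], value)
  channel
}

#' Render a synthetic slide
#'
#' Deterministic given the spec's seed: returns the image, the spot grid and
#' full ground truth (per spot and per nucleus). The truth call applies the
#' default annotation rule to the constructed counts: spots with fewer than
#' 10 nuclei are excluded; otherwise positive iff more than 10% of nuclei
#' carry marker foci (which by construction also satisfy the intensity
#' criterion).
#'
#' @param spec A [scene_spec()].
#' @return List with `image` ([slide_image()]), `grid` (`spot_grid`) and
#'   `truth` (list of tibbles `spots` and `nuclei`).
#' @export
render_slide <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    red <- matrix(0, H, W); green <- matrix(0, H, W); blue <- matrix(0, H, W)
    if (spec$noise_sd > 0) {
      red <- matrix(pmax(0, stats::rnorm(H * W, 0, spec$noise_sd)), H, W)
      green <- matrix(pmax(0, stats::rnorm(H * W, 0, spec$noise_sd)), H, W)
      blue <- matrix(pmax(0, stats::rnorm(H * W, 0, spec$noise_sd)), H, W)
    }
    r_px <- spot_radius_px(spec$diameter_um, spec$microns_per_pixel)
    nuclei_rows <- list()
    spot_rows <- list()
    for (s in seq_len(nrow(spec$spots))) {
      row <- spec$spots[s, ]
      barcode <- sprintf("SPOT-%03d", s)
      sites <- hex_positions(row$center_x, row$center_y, r_px,
                             spec$hex_spacing_px, margin = 5)
      if (row$n_nuclei > nrow(sites)) {
        stop("spot ", barcode, " is overcrowded: ", row$n_nuclei,
             " nuclei requested but only ", nrow(sites),
             " placements fit without exceeding the overlap limit",
             call. = FALSE)
      }
      n <- row$n_nuclei
      pick <- if (n > 0L) sites[sample.int(nrow(sites), n), , drop = FALSE]
              else matrix(numeric(0), 0, 2)
      if (n > 0L) {
        pick <- pick + matrix(stats::runif(2 * n, -spec$jitter_px,
                                           spec$jitter_px), n, 2)
      }
      n_pos <- round(row$positive_fraction * n)
      positive <- rep(FALSE, n)
      if (n_pos > 0L) positive[sample.int(n, n_pos)] <- TRUE
      for (k in seq_len(n)) {
        peak <- stats::runif(1, spec$peak_range[1], spec$peak_range[2])
        blue <- paint_gaussian(blue, pick[k, 1], pick[k, 2],
                               spec$nucleus_sigma_px, peak)
        if (positive[k]) {
          for (f in seq_len(spec$n_foci)) {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- stats::runif(1, 0, spec$nucleus_sigma_px)
            red <- paint_disk(red, pick[k, 1] + rad * cos(ang),
                              pick[k, 2] + rad * sin(ang),
                              spec$focus_radius_px, spec$focus_intensity)
          }
        }
        nuclei_rows[[length(nuclei_rows) + 1L]] <- tibble::tibble(
          barcode = barcode, x = pick[k, 1], y = pick[k, 2],
          peak = peak, positive = positive[k]
        )
      }
      truth_call <- if (n < 10L) "excluded"
                    else if (n > 0L && 100 * n_pos / n > 10) "positive"
                    else "negative"
      spot_rows[[length(spot_rows) + 1L]] <- tibble::tibble(
        barcode = barcode, center_x = row$center_x, center_y = row$center_y,
        n_nuclei = n, n_positive = as.integer(n_pos), call = truth_call
      )
    }
    nuclei_truth <- dplyr::bind_rows(nuclei_rows)
    # RBC confounders: bright red, zero blue, no nucleus underneath
    if (spec$n_rbc > 0L) {
      placed <- 0L
      tries <- 0L
      while (placed < spec$n_rbc && tries < 200L * spec$n_rbc) {
        tries <- tries + 1L
        bx <- stats::runif(1, spec$rbc_radius_px, W - 1 - spec$rbc_radius_px)
        by <- stats::runif(1, spec$rbc_radius_px, H - 1 - spec$rbc_radius_px)
        if (nrow(nuclei_truth) > 0L) {
          d <- sqrt((nuclei_truth$x - bx)^2 + (nuclei_truth$y - by)^2)
          if (min(d) < spec$rbc_radius_px + 6 * spec$nucleus_sigma_px) next
        }
        red <- paint_disk(red, bx, by, spec$rbc_radius_px, spec$rbc_intensity)
        ext <- ceiling(spec$rbc_radius_px)
        xs <- max(0, floor(bx) - ext):min(W - 1, ceiling(bx) + ext)
        ys <- max(0, floor(by) - ext):min(H - 1, ceiling(by) + ext)
        inside <- outer((ys - by)^2, (xs - bx)^2, `+`) <= spec$rbc_radius_px^2
        blue[ys + 1L, xs + 1L][inside] <- 0
        placed <- placed + 1L
      }
    }
    px <- array(0L, c(H, W, 3))
    px[, , 1] <- as.integer(pmin(255, round(red)))
    px[, , 2] <- as.integer(pmin(255, round(green)))
    px[, , 3] <- as.integer(pmin(255, round(blue)))
    spots_truth <- dplyr::bind_rows(spot_rows)
    grid <- spot_grid(spots_truth[, c("barcode", "center_x", "center_y")],
                      diameter_um = spec$diameter_um)
    list(
      image = slide_image(px, microns_per_pixel = spec$microns_per_pixel),
      grid = grid,
      truth = list(spots = spots_truth, nuclei = nuclei_truth)
    )
  })
}

#' Generate a synthetic ratings matrix
#'
#' Emulates a multi-observer annotation study: a latent label vector with the
#' pooled prevalence is perturbed per rater so that each rater's empirical
#' positive proportion lands exactly on `round(p_r * n)` (within 0.5
#' percentage points of the target by construction), with `flip_rate`
#' controlling extra disagreement beyond what the marginals force.
#'
#' @param n_subjects Number of subjects N.
#' @param positive_props Per-rater target positive proportions in [0, 1].
#' @param flip_rate Fraction of labels each rater flips relative to the
#'   latent vector (default 0 = perfect agreement up to marginal shifts).
#' @param seed Integer seed.
#' @return A `ratings_matrix` with labels `"positive"`/`"negative"`.
#' @export
make_ratings <- function(n_subjects, positive_props, flip_rate = 0, seed) {
  stopifnot(n_subjects >= 1, length(positive_props) >= 2,
            all(positive_props >= 0 & positive_props <= 1),
            flip_rate >= 0, flip_rate <= 1)
  withr::with_seed(seed, {
    N <- as.integer(n_subjects)
    n_lat <- round(mean(positive_props) * N)
    z <- rep(FALSE, N)
    if (n_lat > 0L) z[sample.int(N, n_lat)] <- TRUE
    labels <- matrix("", N, length(positive_props))
    for (r in seq_along(positive_props)) {
      delta <- round(positive_props[r] * N) - n_lat
      flips <- max(round(flip_rate * N), abs(delta))
      if ((flips - abs(delta)) %% 2L == 1L) flips <- flips + 1L
      f01 <- (flips + delta) / 2  # negative -> positive
      f10 <- (flips - delta) / 2  # positive -> negative
      if (f01 > sum(!z) || f10 > sum(z)) {
        stop("infeasible marginal/agreement combination for rater ", r,
             call. = FALSE)
      }
      lab <- z
      if (f01 > 0) lab[sample(which(!z), f01)] <- TRUE
      if (f10 > 0) lab[sample(which(z), f10)] <- FALSE
      labels[, r] <- ifelse(lab, "positive", "negative")
    }
    colnames(labels) <- paste0("rater", seq_along(positive_props))
    structure(
      list(subjects = sprintf("S%05d", seq_len(N)), labels = labels),
      class = "ratings_matrix"
    )
  })
}
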