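# Independent brute-force references. These deliberately share no code with
# the package: naive stack-based flood fill, per-pixel loops.

# 8-connected labeling by raster-scan flood fill; labels numbered in the
# order their first (row-major) pixel is encountered
oracle_flood_label <- function(bw) {
  H <- nrow(bw)
  W <- ncol(bw)
  lab <- matrix(0L, H, W)
  next_lab <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (bw[i, j] && lab[i, j] == 0L) {
        next_lab <- next_lab + 1L
        stack <- list(c(i, j))
        lab[i, j] <- next_lab
        while (length(stack) > 0L) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          for (di in -1:1) for (dj in -1:1) {
            ni <- p[1] + di
            nj <- p[2] + dj
            if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
                bw[ni, nj] && lab[ni, nj] == 0L) {
              lab[ni, nj] <- next_lab
              stack[[length(stack) + 1L]] <- c(ni, nj)
            }
          }
        }
      }
    }
  }
  lab
}

# boundary pixels: member pixels with a 4-neighbor outside the set
oracle_boundary <- function(L) {
  H <- nrow(L)
  W <- ncol(L)
  n <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (!L[i, j]) next
      up <- if (i > 1) L[i - 1, j] else FALSE
      down <- if (i < H) L[i + 1, j] else FALSE
      left <- if (j > 1) L[i, j - 1] else FALSE
      right <- if (j < W) L[i, j + 1] else FALSE
      if (!(up && down && left && right)) n <- n + 1L
    }
  }
  n
}

# full peeling reference on a masked grayscale matrix; returns a list of
# nuclei, each list(pixels = 2-col 0-based (x, y), area, boundary, threshold)
oracle_segment <- function(working, params) {
  out <- list()
  threshold <- params$dapi_start_threshold
  while (threshold <= params$dapi_upper_limit && any(working > 0L)) {
    working[working < threshold] <- 0L
    lab <- oracle_flood_label(working > 0L)
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < params$min_area_px) next
      L <- matrix(FALSE, nrow(working), ncol(working))
      L[idx] <- TRUE
      b <- oracle_boundary(L)
      if (b > params$perimeter_max) next
      out[[length(out) + 1L]] <- list(
        pixels = cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L),
        area = nrow(idx), boundary = b, threshold = threshold
      )
      working[idx] <- 0L
    }
    threshold <- threshold + params$range_increment
  }
  out
}

# canonical form for comparing nucleus sets exactly
nucleus_signature <- function(pixels_xy, dims) {
  sort(pixels_xy[, 2] * dims[2] + pixels_xy[, 1])
}

# per-pixel loops for the four spot measurements, given segmented nuclei
oracle_quantify <- function(tile, nuclei, marker) {
  H <- nrow(tile$mask)
  W <- ncol(tile$mask)
  pos <- matrix(FALSE, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (!tile$mask[i, j]) next
      ok <- TRUE
      for (c in 1:3) {
        v <- tile$tile[i, j, c]
        if (v < marker$rgb_min[c] || v > marker$rgb_max[c]) ok <- FALSE
      }
      pos[i, j] <- ok
    }
  }
  n <- nrow(nuclei)
  npos_cells <- 0L
  sum_int <- 0
  n_int <- 0L
  in_nuc <- matrix(FALSE, H, W)
  for (k in seq_len(n)) {
    px <- nuclei$pixels[[k]]
    cnt <- 0L
    for (q in seq_len(nrow(px))) {
      i <- px[q, 2] + 1L
      j <- px[q, 1] + 1L
      in_nuc[i, j] <- TRUE
      if (pos[i, j]) cnt <- cnt + 1L
    }
    if (cnt / nrow(px) >= marker$cell_positive_pixel_fraction) {
      npos_cells <- npos_cells + 1L
    }
  }
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (in_nuc[i, j] && pos[i, j]) {
        sum_int <- sum_int + tile$tile[i, j, tile$main_channel]
        n_int <- n_int + 1L
      }
    }
  }
  list(
    n_cells = n,
    n_positive_cells = npos_cells,
    pct_positive = if (n > 0) 100 * npos_cells / n else 0,
    spot_intensity = if (n_int > 0) sum_int / n_int else 0
  )
}

# two-rater chance-corrected agreement with pooled category prevalences
# (Scott's pi), the closed form the generic multi-rater formula reduces to
# at R = 2
oracle_two_rater_kappa <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  po <- mean(a == b)
  pe <- sum(vapply(cats, function(cc) ((mean(a == cc) + mean(b == cc)) / 2)^2,
                   numeric(1)))
  (po - pe) / (1 - pe)
}
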