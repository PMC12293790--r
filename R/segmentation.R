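#' Segmentation parameters
#'
#' Controls the iterative DAPI-threshold "peeling" segmentation. Starting at
#' `dapi_start_threshold`, pixels below the threshold are deleted, surviving
#' 8-connected regions whose boundary fits within `perimeter_max` are accepted
#' as single nuclei and erased, and the threshold is raised by
#' `range_increment` for the next pass. Because DAPI intensity falls off from
#' the nucleus center to its edge, raising the threshold progressively splits
#' fused nuclei at their dim junctions.
#'
#' @param dapi_start_threshold First DAPI threshold, 0--255 (default 40).
#' @param range_increment Per-iteration threshold increase, >= 1 (default 10);
#'   the "range" knob: finer steps resolve heavier overlaps at more cost.
#' @param dapi_upper_limit Last threshold considered, <= 255 (default 255).
#' @param perimeter_max Maximum boundary-pixel count for a region to be
#'   accepted as one nucleus (default 120). The boundary is counted with
#'   4-neighborhood; regions bigger than one plausible nucleus are held back
#'   for later, higher-threshold passes.
#' @param min_area_px Noise floor: surviving regions smaller than this many
#'   pixels are never accepted (default 20).
#' @param dilate_px Optional radius (px) by which accepted nucleus pixel sets
#'   are grown back toward their full first-iteration footprint before marker
#'   quantification; 0 (default) records the core pixels at the acceptance
#'   threshold.
#' @return A `seg_params` list.
#' @export
seg_params <- function(dapi_start_threshold = 40L, range_increment = 10L,
                       dapi_upper_limit = 255L, perimeter_max = 120L,
                       min_area_px = 20L, dilate_px = 0L) {
  p <- list(
    dapi_start_threshold = as.integer(dapi_start_threshold),
    range_increment = as.integer(range_increment),
    dapi_upper_limit = as.integer(dapi_upper_limit),
    perimeter_max = as.integer(perimeter_max),
    min_area_px = as.integer(min_area_px),
    dilate_px = as.integer(dilate_px)
  )
  stopifnot(
    p$dapi_start_threshold >= 0L, p$dapi_start_threshold <= 255L,
    p$dapi_upper_limit <= 255L,
    p$dapi_start_threshold < p$dapi_upper_limit,
    p$range_increment >= 1L,
    p$perimeter_max >= 1L,
    p$min_area_px >= 1L,
    p$dilate_px >= 0L
  )
  structure(p, class = "seg_params")
}

# 8-connected component labels for a logical matrix; components are numbered
# in raster-scan order (by row, then column) of their first pixel
label_components_8 <- function(bw) {
  H <- nrow(bw)
  W <- ncol(bw)
  lab <- matrix(0L, H, W)
  idx <- which(bw)
  n <- length(idx)
  if (n == 0L) return(lab)
  pos <- integer(H * W)
  pos[idx] <- seq_len(n)
  row <- ((idx - 1L) %% H) + 1L
  col <- ((idx - 1L) %/% H) + 1L
  pair_list <- vector("list", 4L)
  dirs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(dirs)) {
    di <- dirs[[k]][1]
    dj <- dirs[[k]][2]
    ok <- row + di >= 1L & row + di <= H & col + dj <= W
    nb <- idx[ok] + di + dj * H
    hit <- bw[nb]
    if (any(hit)) {
      pair_list[[k]] <- cbind(pos[idx[ok][hit]], pos[nb[hit]])
    }
  }
  edges <- do.call(rbind, pair_list)
  if (is.null(edges)) {
    memb <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  }
  # renumber components by raster-scan order of their top-left pixel
  rmaj <- (row - 1L) * W + col
  first <- tapply(rmaj, memb, min)
  rank <- integer(length(first))
  rank[order(first)] <- seq_along(first)
  lab[idx] <- rank[memb]
  lab
}

#' Boundary length of a pixel region
#'
#' Number of member pixels with at least one 4-neighbor outside the region —
#' the pixel count that "encompasses" a nucleus, compared against the
#' `perimeter_max` acceptance parameter.
#'
#' @param pixels Either a logical matrix marking the region, or a 2-column
#'   matrix/data frame of 0-based `(x, y)` pixel coordinates.
#' @param dim Tile dimensions `c(h, w)`; required for coordinate input.
#' @return Integer boundary-pixel count.
#' @export
boundary_length <- function(pixels, dim = NULL) {
  if (is.logical(pixels) && is.matrix(pixels)) {
    L <- pixels
  } else {
    pixels <- as.matrix(pixels)
    if (nrow(pixels) == 0L) stop("empty pixel set", call. = FALSE)
    if (is.null(dim)) {
      dim <- c(max(pixels[, 2]) + 2L, max(pixels[, 1]) + 2L)
    }
    L <- matrix(FALSE, dim[1], dim[2])
    L[cbind(pixels[, 2] + 1L, pixels[, 1] + 1L)] <- TRUE
  }
  if (!any(L)) stop("empty pixel set", call. = FALSE)
  H <- nrow(L)
  W <- ncol(L)
  pad <- function(di, dj) {
    s <- matrix(FALSE, H, W)
    s[max(1L, 1L + di):min(H, H + di), max(1L, 1L + dj):min(W, W + dj)] <-
      L[max(1L, 1L - di):min(H, H - di), max(1L, 1L - dj):min(W, W - dj)]
    s
  }
  interior <- L & pad(1L, 0L) & pad(-1L, 0L) & pad(0L, 1L) & pad(0L, -1L)
  sum(L) - sum(interior)
}

new_nucleus_tbl <- function(rows) {
  if (length(rows) == 0L) {
    return(tibble::tibble(
      centroid_x = numeric(), centroid_y = numeric(),
      area_px = integer(), boundary_px = integer(),
      accept_threshold = integer(), pixels = list()
    ))
  }
  dplyr::bind_rows(rows)
}

#' One peeling iteration
#'
#' Deletes pixels below `threshold` from the working nuclear-channel image,
#' labels the surviving 8-connected regions, and accepts as nuclei those with
#' `min_area_px <= area` and `boundary_length <= perimeter_max`. Accepted
#' regions are erased from the returned working image; everything else
#' survives (above threshold) into the next iteration.
#'
#' @param working Integer matrix: masked nuclear-channel tile.
#' @param threshold Current DAPI threshold (0--255).
#' @param params [seg_params()].
#' @return List with `accepted` (a nucleus tibble: `centroid_x`, `centroid_y`,
#'   `area_px`, `boundary_px`, `accept_threshold`, list-column `pixels` of
#'   0-based `(x, y)` coordinates) and `remaining` (the updated working image).
#' @export
peel_iteration <- function(working, threshold, params = seg_params()) {
  stopifnot(is.matrix(working), threshold >= 0, threshold <= 255)
  remaining <- working
  remaining[remaining < threshold] <- 0L
  surv <- remaining > 0L
  lab <- label_components_8(surv)
  ncomp <- max(lab)
  rows <- list()
  if (ncomp > 0L) {
    W <- ncol(lab)
    for (k in seq_len(ncomp)) {
      comp_idx <- which(lab == k)
      area <- length(comp_idx)
      if (area < params$min_area_px) next
      L <- matrix(FALSE, nrow(lab), W)
      L[comp_idx] <- TRUE
      b <- boundary_length(L)
      if (b > params$perimeter_max) next
      ri <- ((comp_idx - 1L) %% nrow(lab)) + 1L
      ci <- ((comp_idx - 1L) %/% nrow(lab)) + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        centroid_x = mean(ci - 1L),
        centroid_y = mean(ri - 1L),
        area_px = area,
        boundary_px = as.integer(b),
        accept_threshold = as.integer(threshold),
        pixels = list(cbind(x = ci - 1L, y = ri - 1L))
      )
      remaining[comp_idx] <- 0L
    }
  }
  list(accepted = new_nucleus_tbl(rows), remaining = remaining)
}

#' Segment nuclei in a spot tile by iterative threshold peeling
#'
#' Runs [peel_iteration()] at thresholds `dapi_start_threshold`,
#' `+range_increment`, ... until the threshold exceeds `dapi_upper_limit` or
#' the working image is black. Accepted nuclei accumulate in acceptance order
#' with pairwise-disjoint pixel sets. Deterministic: components are processed
#' in raster-scan order and no randomness is involved.
#'
#' @param tile A `spot_tile` from [extract_spot_tile()].
#' @param params [seg_params()].
#' @return Nucleus tibble (see [peel_iteration()]) with additional slide
#'   coordinates `slide_x`, `slide_y`.
#' @export
segment_nuclei <- function(tile, params = seg_params()) {
  stopifnot(inherits(tile, "spot_tile"))
  working <- masked_channel(tile, tile$nuclear_channel)
  original <- working
  threshold <- params$dapi_start_threshold
  acc <- list()
  while (threshold <= params$dapi_upper_limit && any(working > 0L)) {
    step <- peel_iteration(working, threshold, params)
    if (nrow(step$accepted) > 0L) acc[[length(acc) + 1L]] <- step$accepted
    working <- step$remaining
    threshold <- threshold + params$range_increment
  }
  nuclei <- new_nucleus_tbl(acc)
  if (params$dilate_px > 0L && nrow(nuclei) > 0L) {
    nuclei <- dilate_nuclei(nuclei, original, tile$mask, params)
  }
  nuclei$slide_x <- nuclei$centroid_x + tile$origin_x
  nuclei$slide_y <- nuclei$centroid_y + tile$origin_y
  nuclei
}

# grow each accepted pixel set by a disk, restricted to in-mask pixels that
# were above the start threshold and are not claimed by another nucleus;
# claims are resolved in acceptance order
dilate_nuclei <- function(nuclei, original, mask, params) {
  H <- nrow(original)
  W <- ncol(original)
  eligible <- mask & original >= params$dapi_start_threshold
  claimed <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(nuclei))) {
    claimed[cbind(nuclei$pixels[[i]][, 2] + 1L, nuclei$pixels[[i]][, 1] + 1L)] <- TRUE
  }
  r <- params$dilate_px
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  for (i in seq_len(nrow(nuclei))) {
    px <- nuclei$pixels[[i]]
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(k) {
      cbind(px[, 1] + offs$dx[k], px[, 2] + offs$dy[k])
    })))
    keep <- cand[, 1] >= 0L & cand[, 1] < W & cand[, 2] >= 0L & cand[, 2] < H
    cand <- cand[keep, , drop = FALSE]
    ij <- cbind(cand[, 2] + 1L, cand[, 1] + 1L)
    ok <- eligible[ij] & !claimed[ij]
    add <- cand[ok, , drop = FALSE]
    if (nrow(add) > 0L) {
      claimed[cbind(add[, 2] + 1L, add[, 1] + 1L)] <- TRUE
      newpx <- rbind(px, cbind(x = add[, 1], y = add[, 2]))
      nuclei$pixels[[i]] <- newpx
      nuclei$area_px[i] <- nrow(newpx)
      nuclei$centroid_x[i] <- mean(newpx[, 1])
      nuclei$centroid_y[i] <- mean(newpx[, 2])
    }
  }
  nuclei
}
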