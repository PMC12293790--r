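#' Marker-positivity parameters
#'
#' A pixel is marker-positive when every RGB channel lies inside the closed
#' `[rgb_min, rgb_max]` range — the fluorescence signature of the marker
#' fluorophore, set against proper biological controls. A cell is positive
#' when enough of its nucleus pixels are positive: by default a fraction
#' (`cell_positive_pixel_fraction`), optionally an absolute pixel count.
#'
#' @param rgb_min,rgb_max Length-3 integer vectors (0--255), component-wise
#'   `rgb_min <= rgb_max`. Default `rgb_min = c(100, 0, 0)`,
#'   `rgb_max = c(255, 255, 255)`: a red fluorophore (e.g. Texas Red) calls a
#'   pixel positive when its red channel is bright, whatever the counterstain
#'   underneath.
#' @param cell_positive_pixel_fraction Fraction of a nucleus's pixels that
#'   must be positive for the cell to be positive, in (0, 1]; default 0.10.
#' @param cell_positive_mode `"fraction"` (default) or `"count"`.
#' @param cell_positive_pixel_count Absolute threshold used when
#'   `cell_positive_mode = "count"`.
#' @param intensity_scope `"nuclei"` (default): spot intensity averages the
#'   main channel over marker-positive pixels inside segmented nuclei, which
#'   excludes red-blood-cell autofluorescence (bright red signal with no
#'   nucleus underneath). `"spot"` averages over all marker-positive pixels
#'   in the spot disk instead.
#' @return A `marker_params` list.
#' @export
marker_params <- function(rgb_min = c(100L, 0L, 0L),
                          rgb_max = c(255L, 255L, 255L),
                          cell_positive_pixel_fraction = 0.10,
                          cell_positive_mode = c("fraction", "count"),
                          cell_positive_pixel_count = 10L,
                          intensity_scope = c("nuclei", "spot")) {
  rgb_min <- as.integer(rgb_min)
  rgb_max <- as.integer(rgb_max)
  stopifnot(
    length(rgb_min) == 3L, length(rgb_max) == 3L,
    all(rgb_min >= 0L), all(rgb_max <= 255L),
    all(rgb_min <= rgb_max),
    cell_positive_pixel_fraction > 0, cell_positive_pixel_fraction <= 1,
    cell_positive_pixel_count >= 1L
  )
  structure(
    list(
      rgb_min = rgb_min,
      rgb_max = rgb_max,
      cell_positive_pixel_fraction = cell_positive_pixel_fraction,
      cell_positive_mode = match.arg(cell_positive_mode),
      cell_positive_pixel_count = as.integer(cell_positive_pixel_count),
      intensity_scope = match.arg(intensity_scope)
    ),
    class = "marker_params"
  )
}

#' Marker-positive pixel mask
#'
#' @param tile A `spot_tile`.
#' @param params [marker_params()].
#' @return Logical h x w matrix: TRUE where the pixel is inside the spot disk
#'   and every channel lies within its `[rgb_min, rgb_max]` range.
#' @export
pixel_marker_mask <- function(tile, params = marker_params()) {
  stopifnot(inherits(tile, "spot_tile"))
  pos <- tile$mask
  for (c in 1:3) {
    v <- tile$tile[, , c]
    pos <- pos & v >= params$rgb_min[c] & v <= params$rgb_max[c]
  }
  pos
}

#' Classify cells as marker-positive
#'
#' @param nuclei Nucleus tibble from [segment_nuclei()].
#' @param marker_mask Logical mask from [pixel_marker_mask()] on the same tile.
#' @param params [marker_params()].
#' @return Logical vector, one flag per nucleus; positive when the positive
#'   pixels within the nucleus reach the configured fraction (inclusive) or
#'   count.
#' @export
classify_cells <- function(nuclei, marker_mask, params = marker_params()) {
  if (nrow(nuclei) == 0L) return(logical(0))
  npos <- purrr::map_int(nuclei$pixels, function(px) {
    sum(marker_mask[cbind(px[, 2] + 1L, px[, 1] + 1L)])
  })
  if (params$cell_positive_mode == "fraction") {
    npos / nuclei$area_px >= params$cell_positive_pixel_fraction
  } else {
    npos >= params$cell_positive_pixel_count
  }
}

#' Spot marker intensity
#'
#' Mean main-channel value over pixels that are simultaneously inside a
#' segmented nucleus and marker-positive (the default nuclei-restricted
#' scope); 0 when that set is empty. Restricting to nuclei removes
#' nucleus-free autofluorescent confounders (red blood cells) from the
#' measurement.
#'
#' @inheritParams classify_cells
#' @param tile The `spot_tile` the nuclei came from.
#' @return Mean intensity in [0, 255].
#' @export
spot_intensity <- function(tile, nuclei, marker_mask, params = marker_params()) {
  main <- tile$tile[, , tile$main_channel]
  if (params$intensity_scope == "spot") {
    sel <- marker_mask
  } else {
    in_nucleus <- matrix(FALSE, nrow(marker_mask), ncol(marker_mask))
    for (px in nuclei$pixels) {
      in_nucleus[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- TRUE
    }
    sel <- in_nucleus & marker_mask
  }
  if (!any(sel)) return(0)
  mean(main[sel])
}

#' Quantify one spot
#'
#' Composes [segment_nuclei()], [pixel_marker_mask()], [classify_cells()] and
#' [spot_intensity()] into the per-spot measurement record.
#'
#' @param tile A `spot_tile`.
#' @param seg [seg_params()].
#' @param marker [marker_params()].
#' @return One-row tibble: `n_cells`, `n_positive_cells`, `pct_positive`
#'   (0--100; 0 when no cells), `spot_intensity`.
#' @export
quantify_spot <- function(tile, seg = seg_params(), marker = marker_params()) {
  nuclei <- segment_nuclei(tile, seg)
  mm <- pixel_marker_mask(tile, marker)
  flags <- classify_cells(nuclei, mm, marker)
  n <- nrow(nuclei)
  npos <- sum(flags)
  tibble::tibble(
    n_cells = n,
    n_positive_cells = as.integer(npos),
    pct_positive = if (n > 0L) 100 * npos / n else 0,
    spot_intensity = spot_intensity(tile, nuclei, mm, marker)
  )
}
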