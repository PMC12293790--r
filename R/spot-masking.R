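#' Spot radius in pixels
#'
#' Converts the fixed physical spot diameter (55 um on Visium slides) to an
#' integer pixel radius at the image's scale, rounding half up.
#'
#' @param diameter_um Spot diameter in microns; > 0.
#' @param microns_per_pixel Pixel size in microns per pixel; > 0.
#' @return Integer pixel radius (>= 1).
#' @export
spot_radius_px <- function(diameter_um, microns_per_pixel) {
  stopifnot(is.numeric(diameter_um), is.numeric(microns_per_pixel))
  if (diameter_um <= 0 || microns_per_pixel <= 0) {
    stop("diameter and pixel scale must be positive", call. = FALSE)
  }
  r <- as.integer(floor(diameter_um / (2 * microns_per_pixel) + 0.5))
  if (r < 1L) {
    stop("pixel scale too coarse: spot radius rounds below 1 px", call. = FALSE)
  }
  r
}

#' Extract a masked spot tile
#'
#' Cuts the square tile around one spot center and builds the circular spot
#' mask: pixel (px, py) is inside iff (px - cx)^2 + (py - cy)^2 <= r^2 on the
#' integer lattice. Tiles at image borders are clipped; the area outside the
#' image counts as background. All downstream analysis (segmentation, marker
#' quantification) treats pixels outside the mask as intensity 0.
#'
#' @param image A [slide_image()].
#' @param spot One row of a `spot_grid` (list or single-row data frame with
#'   `barcode`, `center_x`, `center_y`, `diameter_um`).
#' @return A `spot_tile`: list with `tile` (h x w x 3 integer array), `mask`
#'   (h x w logical), `origin_x`/`origin_y` (0-based slide coordinates of the
#'   tile's top-left pixel), `spot`, and the channel-role metadata.
#' @export
extract_spot_tile <- function(image, spot) {
  stopifnot(inherits(image, "slide_image"))
  if (is.data.frame(spot)) {
    stopifnot(nrow(spot) == 1L)
    spot <- as.list(spot)
  }
  h <- dim(image$pixels)[1]
  w <- dim(image$pixels)[2]
  cx <- spot$center_x
  cy <- spot$center_y
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1) {
    stop("spot center outside image bounds",
         if (!is.null(spot$barcode)) paste0(" (barcode ", spot$barcode, ")"),
         call. = FALSE)
  }
  r <- spot_radius_px(spot$diameter_um, image$microns_per_pixel)
  # 0-based pixel window, clipped to the image
  x0 <- max(0L, as.integer(round(cx)) - r)
  x1 <- min(w - 1L, as.integer(round(cx)) + r)
  y0 <- max(0L, as.integer(round(cy)) - r)
  y1 <- min(h - 1L, as.integer(round(cy)) + r)
  tile <- image$pixels[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), , drop = FALSE]
  xs <- x0:x1
  ys <- y0:y1
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  mask <- outer(dy2, dx2, `+`) <= r^2
  structure(
    list(
      tile = tile,
      mask = mask,
      origin_x = x0,
      origin_y = y0,
      radius_px = r,
      spot = spot,
      nuclear_channel = image$nuclear_channel,
      main_channel = image$main_channel,
      microns_per_pixel = image$microns_per_pixel
    ),
    class = "spot_tile"
  )
}

#' @export
print.spot_tile <- function(x, ...) {
  cat(sprintf("<spot_tile> %d x %d px, r = %d px, %d mask px (barcode %s)\n",
              nrow(x$mask), ncol(x$mask), x$radius_px, sum(x$mask),
              x$spot$barcode %||% "?"))
  invisible(x)
}

# masked single-channel working copy: outside-mask pixels forced to 0
masked_channel <- function(tile, channel) {
  m <- tile$tile[, , channel]
  m[!tile$mask] <- 0L
  m
}
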