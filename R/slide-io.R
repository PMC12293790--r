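#' Construct a slide image
#'
#' A `slide_image` wraps an 8-bit RGB raster together with channel-role
#' metadata: which channel carries the nuclear counterstain (DAPI; blue by
#' convention) and which carries the marker fluorophore (the "main channel",
#' e.g. red for Texas Red), plus the physical pixel scale.
#'
#' @param pixels Integer array, height x width x 3, values in 0--255.
#' @param nuclear_channel Channel index (1-based) of the nuclear stain.
#'   Default 3 (blue).
#' @param main_channel Channel index (1-based) of the marker fluorophore.
#'   Default 1 (red).
#' @param microns_per_pixel Physical pixel size in microns per pixel; > 0.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, nuclear_channel = 3L, main_channel = 1L,
                        microns_per_pixel) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must have positive height and width", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  nuclear_channel <- as.integer(nuclear_channel)
  main_channel <- as.integer(main_channel)
  if (!nuclear_channel %in% 1:3 || !main_channel %in% 1:3) {
    stop("channel indices must be 1, 2 or 3", call. = FALSE)
  }
  if (nuclear_channel == main_channel) {
    stop("nuclear and main channels must differ", call. = FALSE)
  }
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      is.na(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("`microns_per_pixel` must be a single positive number", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(
      pixels = pixels,
      nuclear_channel = nuclear_channel,
      main_channel = main_channel,
      microns_per_pixel = as.numeric(microns_per_pixel)
    ),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<slide_image> %d x %d px, %.4g um/px (nuclear ch %d, main ch %d)\n",
    d[1], d[2], x$microns_per_pixel, x$nuclear_channel, x$main_channel
  ))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)

#' Load a slide image from TIFF or PNG
#'
#' Reads a 3-channel (RGBA alpha is dropped) raster and attaches channel
#' roles and pixel scale. 16-bit input is rescaled to 8-bit by linear
#' division of the full scale, so all downstream thresholds live on 0--255.
#'
#' @inheritParams slide_image
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A [slide_image()].
#' @export
load_slide_image <- function(path, nuclear_channel = 3L, main_channel = 1L,
                             microns_per_pixel) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (use TIFF or PNG)", call. = FALSE)
  )
  if (length(dim(raw)) == 2L) {
    stop("single-channel image; a 3-channel RGB raster is required", call. = FALSE)
  }
  nch <- dim(raw)[3]
  if (nch > 4L || nch < 3L) {
    stop("image has ", nch, " channels; 3 (RGB) or 4 (RGBA) supported", call. = FALSE)
  }
  if (nch == 4L) raw <- raw[, , 1:3, drop = FALSE]
  # readers return intensities normalised to [0,1] regardless of bit depth,
  # so * 255 is exact for 8-bit input and the linear rescale for 16-bit
  px <- array(as.integer(round(raw * 255)), dim = dim(raw))
  slide_image(px, nuclear_channel, main_channel, microns_per_pixel)
}

#' Write a slide image to disk
#'
#' 8-bit lossless output; the companion of [load_slide_image()] for
#' materialising synthetic fixtures.
#'
#' @param image A [slide_image()].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_slide_image <- function(image, path) {
  stopifnot(inherits(image, "slide_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L, compression = "none"),
    png = png::writePNG(arr, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

spot_dialects <- c("loupe_csv", "tissue_positions", "plain_xy")

new_spot_grid <- function(df, dialect) {
  if (anyDuplicated(df$barcode)) {
    dup <- df$barcode[duplicated(df$barcode)][1]
    stop("duplicate barcode in spot table: ", dup, call. = FALSE)
  }
  if (nrow(df) == 0L) stop("spot table contains no usable spots", call. = FALSE)
  if (!is.numeric(df$center_x) || !is.numeric(df$center_y) ||
      anyNA(df$center_x) || anyNA(df$center_y)) {
    stop("spot coordinates must be numeric and complete", call. = FALSE)
  }
  out <- tibble::new_tibble(df, source_dialect = dialect,
                            class = "spot_grid", nrow = nrow(df))
  out
}

#' Read a spot-center coordinate table
#'
#' Supports the three CSV dialects in circulation: Loupe Browser exports
#' (`Barcode`, `X Coordinate`, `Y Coordinate`), Space Ranger
#' `tissue_positions.csv` (rows with `in_tissue == 0` are dropped;
#' `pxl_col_in_fullres` maps to `center_x`, `pxl_row_in_fullres` to
#' `center_y`), and a plain `id,x,y` table. Coordinates are 0-based pixel
#' indices with x = column (rightward) and y = row (downward).
#'
#' @param path CSV file path.
#' @param dialect One of `"loupe_csv"`, `"tissue_positions"`, `"plain_xy"`.
#' @param diameter_um Physical spot diameter in microns; the Visium spot
#'   size is fixed at 55.
#' @return A `spot_grid` tibble with columns `barcode`, `center_x`,
#'   `center_y`, `diameter_um`.
#' @export
read_spot_table <- function(path, dialect = c("loupe_csv", "tissue_positions", "plain_xy"),
                            diameter_um = 55) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("spot table not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- switch(dialect,
    loupe_csv = c("Barcode", "X Coordinate", "Y Coordinate"),
    tissue_positions = c("barcode", "in_tissue", "array_row", "array_col",
                         "pxl_row_in_fullres", "pxl_col_in_fullres"),
    plain_xy = c("id", "x", "y")
  )
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("spot table is missing required column(s) for dialect '", dialect,
         "': ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- switch(dialect,
    loupe_csv = tibble::tibble(
      barcode = as.character(raw[["Barcode"]]),
      center_x = as.numeric(raw[["X Coordinate"]]),
      center_y = as.numeric(raw[["Y Coordinate"]])
    ),
    tissue_positions = {
      keep <- raw[["in_tissue"]] == 1
      tibble::tibble(
        barcode = as.character(raw[["barcode"]][keep]),
        center_x = as.numeric(raw[["pxl_col_in_fullres"]][keep]),
        center_y = as.numeric(raw[["pxl_row_in_fullres"]][keep])
      )
    },
    plain_xy = tibble::tibble(
      barcode = as.character(raw[["id"]]),
      center_x = as.numeric(raw[["x"]]),
      center_y = as.numeric(raw[["y"]])
    )
  )
  df$diameter_um <- as.numeric(diameter_um)
  new_spot_grid(df, dialect)
}

#' Build a spot grid from a data frame
#'
#' Programmatic companion of [read_spot_table()], mainly used by the
#' synthetic generator and in scripted workflows.
#'
#' @param df Data frame with columns `barcode`, `center_x`, `center_y`.
#' @param diameter_um Spot diameter in microns (recycled if scalar).
#' @return A `spot_grid` tibble.
#' @export
spot_grid <- function(df, diameter_um = 55) {
  stopifnot(all(c("barcode", "center_x", "center_y") %in% names(df)))
  out <- tibble::tibble(
    barcode = as.character(df$barcode),
    center_x = as.numeric(df$center_x),
    center_y = as.numeric(df$center_y),
    diameter_um = if ("diameter_um" %in% names(df)) as.numeric(df$diameter_um)
                  else rep(as.numeric(diameter_um), nrow(df))
  )
  new_spot_grid(out, "plain_xy")
}

#' Write the per-spot results table
#'
#' Fixed schema: `barcode, center_x, center_y, n_cells, n_positive_cells,
#' pct_positive, spot_intensity, call`. Percent positivity is printed with
#' one decimal and spot intensity with two, matching the precision the
#' method reports; `call` is one of `positive`, `negative`, `excluded`.
#'
#' @param results A `spot_annotation` tibble from [run_pipeline()] (or any
#'   data frame with the schema columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  cols <- c("barcode", "center_x", "center_y", "n_cells", "n_positive_cells",
            "pct_positive", "spot_intensity", "call")
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("`results` must be a non-empty data frame", call. = FALSE)
  }
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols) > 0L) {
    stop("results are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(results$call %in% c("positive", "negative", "excluded")))
  out <- data.frame(
    barcode = results$barcode,
    center_x = results$center_x,
    center_y = results$center_y,
    n_cells = results$n_cells,
    n_positive_cells = results$n_positive_cells,
    pct_positive = sprintf("%.1f", results$pct_positive),
    spot_intensity = sprintf("%.2f", results$spot_intensity),
    call = results$call,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Loupe-Browser-importable category CSV
#'
#' Two columns, `Barcode` and the category name, one row per non-excluded
#' spot with value `positive` or `negative`. The file imports directly into
#' Loupe Browser as a spot category, closing the loop between image-based
#' annotation and transcriptomic analysis.
#'
#' @inheritParams write_results_csv
#' @param category Column header for the category (default `"marker"`).
#' @return `path`, invisibly.
#' @export
write_loupe_categories <- function(results, path, category = "marker") {
  stopifnot(is.data.frame(results),
            all(c("barcode", "call") %in% names(results)))
  if (anyNA(results$barcode) || any(!nzchar(results$barcode))) {
    stop("every result must carry a barcode", call. = FALSE)
  }
  keep <- results$call != "excluded"
  out <- data.frame(Barcode = results$barcode[keep],
                    cat = results$call[keep], stringsAsFactors = FALSE)
  names(out)[2] <- category
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
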