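#' Spot call parameters
#'
#' The final per-spot annotation rule. Spots with fewer than `min_cells`
#' segmented nuclei are excluded outright (too few cells to score reliably);
#' the remainder are called positive when the selected criteria exceed their
#' thresholds. The published operating point for gamma-H2AX scoring is
#' intensity above 60 together with more than 10% positive cells.
#'
#' @param mode `"both"` (default: intensity and percent criteria must both
#'   hold), `"intensity_only"`, or `"percent_only"`.
#' @param intensity_threshold Spot marker intensity threshold (default 60).
#' @param percent_threshold Percent positive-cell threshold (default 10).
#' @param min_cells Minimum segmented nuclei for a spot to be scored
#'   (default 10).
#' @param comparison `"gt"` (default; strict `>`) or `"ge"` (`>=`) for both
#'   criteria.
#' @return A `call_params` list.
#' @export
call_params <- function(mode = c("both", "intensity_only", "percent_only"),
                        intensity_threshold = 60,
                        percent_threshold = 10,
                        min_cells = 10L,
                        comparison = c("gt", "ge")) {
  stopifnot(intensity_threshold >= 0, percent_threshold >= 0, min_cells >= 1L)
  structure(
    list(
      mode = match.arg(mode),
      intensity_threshold = as.numeric(intensity_threshold),
      percent_threshold = as.numeric(percent_threshold),
      min_cells = as.integer(min_cells),
      comparison = match.arg(comparison)
    ),
    class = "call_params"
  )
}

#' Call one spot
#'
#' @param m One-row data frame of measurements (`n_cells`,
#'   `n_positive_cells`, `pct_positive`, `spot_intensity`), e.g. from
#'   [quantify_spot()].
#' @param params [call_params()].
#' @return `"positive"`, `"negative"` or `"excluded"`.
#' @export
call_spot <- function(m, params = call_params()) {
  if (is.data.frame(m)) {
    stopifnot(nrow(m) == 1L)
    m <- as.list(m)
  }
  if (m$n_cells < params$min_cells) return("excluded")
  exceeds <- if (params$comparison == "gt") `>` else `>=`
  int_ok <- exceeds(m$spot_intensity, params$intensity_threshold)
  pct_ok <- exceeds(m$pct_positive, params$percent_threshold)
  hit <- switch(params$mode,
    intensity_only = int_ok,
    percent_only = pct_ok,
    both = int_ok && pct_ok
  )
  if (hit) "positive" else "negative"
}

#' Annotate every spot on a slide
#'
#' The whole-slide orchestration: for each spot in the grid, extract the
#' masked tile, segment nuclei, quantify the marker, and apply the call rule.
#' Output order follows grid order and the computation is fully
#' deterministic — identical inputs give identical output bytes.
#'
#' @param image A [slide_image()].
#' @param grid A `spot_grid` from [read_spot_table()] or [spot_grid()].
#' @param seg [seg_params()].
#' @param marker [marker_params()].
#' @param call [call_params()].
#' @return A `spot_annotation` tibble: `barcode`, `center_x`, `center_y`,
#'   `n_cells`, `n_positive_cells`, `pct_positive`, `spot_intensity`, `call`,
#'   one row per spot. The parameter sets travel as attributes.
#' @export
run_pipeline <- function(image, grid,
                         seg = seg_params(),
                         marker = marker_params(),
                         call = call_params()) {
  stopifnot(inherits(image, "slide_image"), is.data.frame(grid))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    spot <- grid[i, ]
    tile <- extract_spot_tile(image, spot)
    m <- quantify_spot(tile, seg, marker)
    tibble::tibble(
      barcode = spot$barcode,
      center_x = spot$center_x,
      center_y = spot$center_y,
      n_cells = m$n_cells,
      n_positive_cells = m$n_positive_cells,
      pct_positive = m$pct_positive,
      spot_intensity = m$spot_intensity,
      call = call_spot(m, call)
    )
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, nrow = nrow(out), class = "spot_annotation",
                     seg_params = seg, marker_params = marker,
                     call_params = call)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a spot annotation
#'
#' @param x A `spot_annotation` from [run_pipeline()].
#' @param ... Unused.
#' @return A plain tibble of per-spot results.
#' @method tidy spot_annotation
#' @export
tidy.spot_annotation <- function(x, ...) {
  tibble::as_tibble(unclass_annotation(x))
}

#' One-row summary of a spot annotation
#'
#' @inheritParams tidy.spot_annotation
#' @return Tibble with spot counts by call, the positive rate among scored
#'   spots (percent), and mean cell count / intensity over scored spots.
#' @method glance spot_annotation
#' @export
glance.spot_annotation <- function(x, ...) {
  scored <- x$call != "excluded"
  tibble::tibble(
    n_spots = nrow(x),
    n_positive = sum(x$call == "positive"),
    n_negative = sum(x$call == "negative"),
    n_excluded = sum(!scored),
    pct_spots_positive = if (any(scored)) 100 * sum(x$call == "positive") / sum(scored) else 0,
    mean_cells = if (any(scored)) mean(x$n_cells[scored]) else 0,
    mean_intensity = if (any(scored)) mean(x$spot_intensity[scored]) else 0
  )
}

unclass_annotation <- function(x) {
  attr(x, "seg_params") <- NULL
  attr(x, "marker_params") <- NULL
  attr(x, "call_params") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Spot map colored by call
#'
#' @param object A `spot_annotation`.
#' @param ... Unused.
#' @return A ggplot: spot centers in image coordinates (y axis flipped to
#'   match raster orientation), colored by call and sized by cell count.
#' @method autoplot spot_annotation
#' @export
autoplot.spot_annotation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$center_x, y = .data$center_y,
    colour = .data$call, size = .data$n_cells
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(
      positive = "#d62728", negative = "#1f77b4", excluded = "grey60"
    )) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "call",
                  size = "nuclei") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL
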