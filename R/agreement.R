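#' Build a ratings matrix from per-rater label tables
#'
#' Each rater contributes a two-column table (spot identifier, label) — for
#' instance a Loupe category CSV written by [write_loupe_categories()].
#' Tables are inner-joined on the identifier: spots missing from any rater
#' are dropped (with a message giving the count), so every retained subject
#' carries a complete set of labels.
#'
#' @param ... Two or more data frames whose first column identifies the spot
#'   and second column carries the label, or a single list of such data
#'   frames.
#' @param raters Optional character vector of rater names.
#' @return A `ratings_matrix`: list with `subjects` (character vector) and
#'   `labels` (N x R character matrix).
#' @export
ratings_matrix <- function(..., raters = NULL) {
  tabs <- list(...)
  if (length(tabs) == 1L && !is.data.frame(tabs[[1]])) tabs <- tabs[[1]]
  if (length(tabs) < 2L) stop("at least two raters are required", call. = FALSE)
  tabs <- lapply(tabs, function(t) {
    stopifnot(is.data.frame(t), ncol(t) >= 2L)
    data.frame(id = as.character(t[[1]]), label = as.character(t[[2]]),
               stringsAsFactors = FALSE)
  })
  ids <- Reduce(intersect, lapply(tabs, function(t) t$id))
  n_all <- length(unique(unlist(lapply(tabs, function(t) t$id))))
  if (length(ids) == 0L) stop("no common subjects across raters", call. = FALSE)
  if (length(ids) < n_all) {
    message(n_all - length(ids), " spot(s) missing from at least one rater dropped")
  }
  labels <- vapply(tabs, function(t) t$label[match(ids, t$id)], character(length(ids)))
  labels <- matrix(labels, nrow = length(ids))
  if (is.null(raters)) raters <- paste0("rater", seq_along(tabs))
  colnames(labels) <- raters
  structure(list(subjects = ids, labels = labels), class = "ratings_matrix")
}

#' Read a two-column ratings CSV
#'
#' Accepts both the Loupe category dialect (`Barcode,<category>`) and any
#' plain two-column id/label CSV.
#'
#' @param path CSV path.
#' @return Tibble with columns `id`, `label`.
#' @export
read_ratings_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2L) stop("ratings CSV needs two columns (id, label)", call. = FALSE)
  tibble::tibble(id = as.character(raw[[1]]), label = as.character(raw[[2]]))
}

as_label_matrix <- function(ratings) {
  if (inherits(ratings, "ratings_matrix")) return(ratings$labels)
  if (is.matrix(ratings)) return(ratings)
  stop("expected a ratings_matrix or a label matrix", call. = FALSE)
}

#' Pairwise percent agreement
#'
#' Percentage of subjects two raters label identically.
#'
#' @param a,b Equal-length label vectors.
#' @return Percent in [0, 100].
#' @export
pairwise_percent_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  if (length(a) == 0L) stop("empty label vectors", call. = FALSE)
  100 * mean(a == b)
}

#' Average pairwise percent agreement
#'
#' Mean of [pairwise_percent_agreement()] over all rater pairs.
#'
#' @param ratings A `ratings_matrix` or an N x R label matrix.
#' @return Percent in [0, 100].
#' @export
average_pairwise_agreement <- function(ratings) {
  labels <- as_label_matrix(ratings)
  R <- ncol(labels)
  if (R < 2L) stop("at least two raters are required", call. = FALSE)
  pairs <- utils::combn(R, 2L)
  mean(apply(pairs, 2L, function(p) {
    pairwise_percent_agreement(labels[, p[1]], labels[, p[2]])
  }))
}

#' Fleiss' kappa
#'
#' Chance-corrected agreement for R raters and any number of categories:
#' with n_ij the raters assigning subject i to category j,
#' P_i = (sum_j n_ij^2 - R) / (R (R - 1)), p_j = sum_i n_ij / (N R),
#' kappa = (mean(P_i) - sum_j p_j^2) / (1 - sum_j p_j^2). Equals 0 at chance
#' agreement and 1 at unanimity. When every assignment falls in a single
#' category the chance term is 1 and agreement is perfect; 1 is returned.
#'
#' @inheritParams average_pairwise_agreement
#' @return Kappa in [-1, 1].
#' @export
fleiss_kappa <- function(ratings) {
  labels <- as_label_matrix(ratings)
  N <- nrow(labels)
  R <- ncol(labels)
  if (N < 1L) stop("no subjects", call. = FALSE)
  if (R < 2L) stop("at least two raters are required", call. = FALSE)
  cats <- sort(unique(as.vector(labels)))
  n_ij <- vapply(cats, function(cc) rowSums(labels == cc), numeric(N))
  n_ij <- matrix(n_ij, nrow = N)
  P_i <- (rowSums(n_ij^2) - R) / (R * (R - 1))
  p_j <- colSums(n_ij) / (N * R)
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (1 - P_e < .Machine$double.eps) {
    return(if (P_bar >= 1 - 1e-12) 1 else NaN)
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Fleiss' kappa for three binary raters from reported summaries
#'
#' Reconstructs kappa from exactly the summaries an agreement table reports:
#' the per-rater positive proportions and the mean pairwise percent
#' agreement. For three raters and binary labels the per-subject agreement
#' P_i equals agreeing-pairs/3, so the mean of P_i is the mean pairwise
#' agreement; the chance term uses the pooled positive proportion,
#' P_e = p^2 + (1 - p)^2 with p = mean of the per-rater proportions.
#'
#' @param positive_props Numeric vector of three per-rater positive
#'   proportions in [0, 1].
#' @param mean_pairwise_agreement Mean pairwise percent agreement (0--100).
#' @return Kappa.
#' @export
fleiss_kappa_binary_from_summaries <- function(positive_props,
                                               mean_pairwise_agreement) {
  stopifnot(length(positive_props) == 3L)
  if (any(positive_props < 0 | positive_props > 1)) {
    stop("positive proportions must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(mean_pairwise_agreement >= 0, mean_pairwise_agreement <= 100)
  p <- mean(positive_props)
  P_bar <- mean_pairwise_agreement / 100
  P_e <- p^2 + (1 - p)^2
  if (1 - P_e < .Machine$double.eps) {
    return(if (P_bar >= 1 - 1e-12) 1 else NaN)
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Interobserver agreement summary
#'
#' Pairwise percent agreement for every rater pair, their average, and
#' Fleiss' kappa in one object, with [tidy()]/[glance()] accessors.
#'
#' @inheritParams average_pairwise_agreement
#' @return An `agreement_summary` list: `pairwise` tibble
#'   (`rater_a`, `rater_b`, `agreement`), `average_pairwise`, `kappa`,
#'   `n_subjects`, `n_raters`.
#' @export
agreement_summary <- function(ratings) {
  labels <- as_label_matrix(ratings)
  R <- ncol(labels)
  if (R < 2L) stop("at least two raters are required", call. = FALSE)
  rn <- colnames(labels)
  if (is.null(rn)) rn <- paste0("rater", seq_len(R))
  pairs <- utils::combn(R, 2L)
  pw <- tibble::tibble(
    rater_a = rn[pairs[1, ]],
    rater_b = rn[pairs[2, ]],
    agreement = apply(pairs, 2L, function(p) {
      pairwise_percent_agreement(labels[, p[1]], labels[, p[2]])
    })
  )
  structure(
    list(
      pairwise = pw,
      average_pairwise = mean(pw$agreement),
      kappa = fleiss_kappa(labels),
      n_subjects = nrow(labels),
      n_raters = R
    ),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("<agreement_summary> %d subjects, %d raters\n",
              x$n_subjects, x$n_raters))
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %s vs %s: %.2f%%\n", x$pairwise$rater_a[i],
                x$pairwise$rater_b[i], x$pairwise$agreement[i]))
  }
  cat(sprintf("  average pairwise agreement: %.2f%%\n", x$average_pairwise))
  cat(sprintf("  Fleiss' kappa: %.3f\n", x$kappa))
  invisible(x)
}

#' @rdname agreement_summary
#' @param x An `agreement_summary`.
#' @param ... Unused.
#' @method tidy agreement_summary
#' @export
tidy.agreement_summary <- function(x, ...) x$pairwise

#' @rdname agreement_summary
#' @method glance agreement_summary
#' @export
glance.agreement_summary <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_raters = x$n_raters,
    average_pairwise = x$average_pairwise,
    kappa = x$kappa
  )
}

#' Pairwise-agreement bar chart
#'
#' @param object An `agreement_summary`.
#' @param ... Unused.
#' @return A ggplot of the pairwise agreement values with the average marked.
#' @method autoplot agreement_summary
#' @export
autoplot.agreement_summary <- function(object, ...) {
  df <- object$pairwise
  df$pair <- paste(df$rater_a, "vs", df$rater_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$agreement)) +
    ggplot2::geom_col(fill = "#1f77b4", width = 0.6) +
    ggplot2::geom_hline(yintercept = object$average_pairwise,
                        linetype = "dashed") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "percent agreement",
                  subtitle = sprintf("average %.2f%%, Fleiss' kappa %.3f",
                                     object$average_pairwise, object$kappa)) +
    ggplot2::theme_minimal()
}
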