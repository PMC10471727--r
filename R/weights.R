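#' Hierarchical observation weights
#'
#' Downweights observations so that sample-size imbalance between regions,
#' glaciers (or spatial clusters) and snow-free-day classes cannot inflate
#' agreement statistics. Within each region the weights sum to 1; each of
#' the region's G groups receives an equal 1/G share; within a group each
#' non-empty sfd category receives an equal 1/(G*M) share, M being the
#' number of non-empty categories of that group; observations inside one
#' (group, category) cell share its mass equally. Empty categories receive
#' no mass and do not inflate the remaining cells.
#'
#' @param df Tibble of observations.
#' @param region,group Column names (strings) of the region and group
#'   (glacier or spatial-cluster) labels.
#' @param category Optional column name of a pre-made category label. If
#'   `NULL` (default), categories are deciles of the `sfd` column on the
#'   0--100% scale (`category_edges`).
#' @param category_edges Breaks for the sfd classification, default
#'   `seq(0, 100, 10)`.
#' @return The input tibble with `.category` and `weight` columns appended.
#' @export
build_weights <- function(df, region = "region", group = "glacier_id",
                          category = NULL, category_edges = seq(0, 100, by = 10)) {
  for (col in c(region, group)) {
    if (!col %in% names(df)) stop("missing label column: ", col, call. = FALSE)
    if (anyNA(df[[col]])) {
      stop("observation(s) with missing ", col, " label: rows ",
           paste(utils::head(which(is.na(df[[col]])), 5), collapse = ", "),
           call. = FALSE)
    }
  }
  if (is.null(category)) {
    if (!"sfd" %in% names(df)) {
      stop("no category column given and no sfd column to classify", call. = FALSE)
    }
    if (anyNA(df$sfd)) stop("observation(s) with missing sfd", call. = FALSE)
    cat_lab <- as.character(cut(df$sfd, breaks = category_edges,
                                include.lowest = TRUE, right = TRUE))
  } else {
    if (!category %in% names(df)) stop("missing label column: ", category, call. = FALSE)
    if (anyNA(df[[category]])) {
      stop("observation(s) with missing ", category, " label", call. = FALSE)
    }
    cat_lab <- as.character(df[[category]])
  }
  out <- df
  out$.category <- cat_lab
  out$.region <- as.character(df[[region]])
  out$.group <- as.character(df[[group]])

  out <- out |>
    dplyr::group_by(.data$.region) |>
    dplyr::mutate(.G = dplyr::n_distinct(.data$.group)) |>
    dplyr::group_by(.data$.region, .data$.group) |>
    dplyr::mutate(.M = dplyr::n_distinct(.data$.category)) |>
    dplyr::group_by(.data$.region, .data$.group, .data$.category) |>
    dplyr::mutate(weight = 1 / (.data$.G * .data$.M * dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::select(-".G", -".M", -".region", -".group")
  out
}

#' Weighted agreement statistics
#'
#' Agreement between observed and predicted values under observation
#' weights: `wR2` is the coefficient of determination of the weighted
#' linear regression of observed on predicted (slope and intercept free),
#' `wMAE = sum(w |e|) / sum(w)` and `wRMSE = sqrt(sum(w e^2) / sum(w))`
#' with `e = observed - predicted`. All three are invariant to rescaling
#' the weights.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3).
#' @param weights Positive observation weights.
#' @return Tibble with `wr2`, `wmae`, `wrmse`. `wr2` is `NA` when the
#'   predictions have zero variance (errors are still reported).
#' @export
weighted_stats <- function(observed, predicted, weights) {
  n <- length(observed)
  if (length(predicted) != n || length(weights) != n) {
    stop("observed, predicted and weights must have equal length", call. = FALSE)
  }
  if (n < 3) stop("at least 3 observations are required", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  e <- observed - predicted
  w <- weights / sum(weights)
  wmae <- sum(w * abs(e))
  wrmse <- sqrt(sum(w * e^2))
  wr2 <- if (stats::var(predicted) == 0) {
    NA_real_
  } else {
    # a perfect fit triggers a harmless precision warning in summary.lm
    suppressWarnings(
      summary(stats::lm(observed ~ predicted, weights = weights))$r.squared
    )
  }
  tibble::tibble(wr2 = wr2, wmae = wmae, wrmse = wrmse)
}
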