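#' Project soil temperature over new locations and months
#'
#' Applies a fixed-coefficient vector (typically the mean leave-one-out
#' coefficients) to a table of raw covariates, with no random effect.
#' Projection is at 5 cm depth unless stated otherwise. Cells with
#' `sfd <= sfd_cutoff` (snow-decoupled) or, when an `n_images` column is
#' present, with fewer than `min_images` supporting images, are masked to
#' `NA`.
#'
#' @param coefficients Named fixed-coefficient vector (standardized scale)
#'   over [model_term_names()].
#' @param standardization Training standardization tibble (from
#'   [build_design()] / an `fc_loo`).
#' @param covariates Tibble with `mT`, `rad`, `sfd`, `dg` (m), `tc`, `pf`
#'   and any id columns; optional `n_images`.
#' @param depth_cm Projection depth, cm (default 5).
#' @param sfd_cutoff Masking cutoff for snow-decoupled cells (default 20).
#' @param min_images Minimum satellite images behind an sfd value
#'   (default 15), applied only when `n_images` is present.
#' @return `covariates` with a `.pred` column (`NA` where masked).
#' @export
project_soil_temperature <- function(coefficients, standardization, covariates,
                                     depth_cm = 5, sfd_cutoff = 20,
                                     min_images = 15) {
  df <- dplyr::mutate(tibble::as_tibble(covariates), depth_cm = depth_cm)
  xs <- standardize_design(df, standardization)
  mm <- model_matrix_fixed(xs)
  pred <- as.vector(mm %*% coefficients[colnames(mm)])
  masked <- df$sfd <= sfd_cutoff
  if ("n_images" %in% names(df)) {
    masked <- masked | df$n_images < min_images
  }
  dplyr::mutate(tibble::as_tibble(covariates),
                .pred = ifelse(masked, NA_real_, pred))
}

#' Stratified sampling of projection points by distance class
#'
#' Lays a regular square grid of `grid_size` meters over the candidate
#' cells (equal-area projected coordinates assumed), assigns each candidate
#' to its distance class, samples `points_per_class` cells per class
#' without replacement within every grid cell, and drops entirely any grid
#' cell that cannot supply the full complement
#' (`points_per_class x number of classes`).
#'
#' @param candidates Tibble with `x`, `y` (meters, equal-area CRS) and
#'   `distance` (m from the most recent glacier outline); rows with `NA`
#'   distance are ignored.
#' @param grid_size Sampling-grid cell size, m (default 50 km).
#' @param classes Two-column matrix-like of distance class bounds, default
#'   the five bands 0-100, 400-600, 900-1100, 1900-2100, 2900-3100 m.
#' @param points_per_class Points sampled per class per cell (default 2).
#' @param seed Mandatory integer seed for the sampling stream.
#' @return Tibble of sampled points with `cell_id`, `distance_class`,
#'   `x`, `y`, `distance`.
#' @export
stratified_sample <- function(candidates, grid_size = 50000,
                              classes = distance_classes(),
                              points_per_class = 2, seed) {
  if (missing(seed)) stop("seed is mandatory for stratified sampling", call. = FALSE)
  cand <- candidates |>
    dplyr::filter(!is.na(.data$distance)) |>
    dplyr::mutate(
      cell_id = paste0(floor(.data$x / grid_size), "_", floor(.data$y / grid_size)),
      distance_class = classify_distance(.data$distance, classes)
    ) |>
    dplyr::filter(!is.na(.data$distance_class))
  if (nrow(cand) == 0) stop("no valid candidate cells to sample", call. = FALSE)
  need <- points_per_class * nrow(classes)
  set.seed(as.integer(seed))
  out <- cand |>
    dplyr::group_by(.data$cell_id, .data$distance_class) |>
    dplyr::slice_sample(n = points_per_class, replace = FALSE) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::filter(dplyr::n() == need) |>
    dplyr::ungroup()
  if (nrow(out) == 0) stop("no grid cell could supply all distance classes", call. = FALSE)
  out
}

#' @rdname stratified_sample
#' @export
distance_classes <- function() {
  tibble::tibble(
    lower = c(0, 400, 900, 1900, 2900),
    upper = c(100, 600, 1100, 2100, 3100),
    label = c("0-100", "400-600", "900-1100", "1900-2100", "2900-3100")
  )
}

classify_distance <- function(distance, classes = distance_classes()) {
  out <- rep(NA_character_, length(distance))
  for (i in seq_len(nrow(classes))) {
    sel <- !is.na(distance) & distance >= classes$lower[i] & distance <= classes$upper[i]
    out[sel] <- classes$label[i]
  }
  factor(out, levels = classes$label)
}

#' Latitudinal band of a point
#'
#' `Northern` and `Southern` are the areas poleward of the Tropics
#' (23.44 deg); `Inter-tropical` is the zone between them.
#'
#' @param lat Latitude, decimal degrees.
#' @return Factor with levels Northern, Inter-tropical, Southern.
#' @export
latitude_band <- function(lat) {
  factor(
    ifelse(lat > 23.44, "Northern",
           ifelse(lat < -23.44, "Southern", "Inter-tropical")),
    levels = c("Northern", "Inter-tropical", "Southern")
  )
}

#' Per-point microclimate change between two periods
#'
#' `delta_t = mean(late months) - mean(early months)` over the selected
#' season; months masked (`NA`) in either period are excluded pairwise from
#' both means, so the difference is always computed on shared months.
#' Seasons are the standard climatological quarters; December is grouped
#' with the following January and February.
#'
#' @param temps Tibble with `point_id`, `period` (`"early"`/`"late"`),
#'   `month` (1--12) and `temperature` (possibly `NA` where masked).
#' @param season `"annual"` (default), `"DJF"`, `"MAM"`, `"JJA"`, `"SON"`.
#' @return Tibble with `point_id`, `t_early`, `t_late`, `delta_t`,
#'   `n_months` (shared months used; `delta_t` is `NA` when none).
#' @export
delta_t <- function(temps, season = c("annual", "DJF", "MAM", "JJA", "SON")) {
  season <- match.arg(season)
  keep <- switch(season,
    annual = 1:12, DJF = c(12, 1, 2), MAM = 3:5, JJA = 6:8, SON = 9:11
  )
  wide <- temps |>
    dplyr::filter(.data$month %in% keep) |>
    tidyr::pivot_wider(
      id_cols = c("point_id", "month"),
      names_from = "period", values_from = "temperature",
      # several years per period collapse to the period's month mean
      values_fn = function(x) mean(x, na.rm = TRUE)
    ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ ifelse(is.nan(.x), NA, .x)))
  if (!all(c("early", "late") %in% names(wide))) {
    stop("temps must contain both periods 'early' and 'late'", call. = FALSE)
  }
  wide |>
    dplyr::filter(!is.na(.data$early), !is.na(.data$late)) |>
    dplyr::group_by(.data$point_id) |>
    dplyr::summarise(
      t_early = mean(.data$early),
      t_late = mean(.data$late),
      n_months = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(delta_t = .data$t_late - .data$t_early) |>
    dplyr::right_join(
      dplyr::distinct(temps, .data$point_id),
      by = "point_id"
    )
}

#' Spatial microclimate variability within a buffer
#'
#' The 80% inter-percentile range (q90 - q10, type-7 quantiles) of the
#' period-mean annual temperature over all raster cells whose centers lie
#' within `radius` of the point. Points supported by fewer than `min_cells`
#' valid cells return `NA`.
#'
#' @param points Tibble with `point_id`, `x`, `y` (meters).
#' @param cells Tibble with `x`, `y`, `temperature` (period-mean annual).
#' @param radius Buffer radius, m (default 250).
#' @param min_cells Minimum valid cells in the buffer (default 5).
#' @return `points` with a `t_var` column appended (deg C, >= 0).
#' @export
t_var <- function(points, cells, radius = 250, min_cells = 5) {
  vals <- purrr::map_dbl(seq_len(nrow(points)), function(i) {
    d2 <- (cells$x - points$x[i])^2 + (cells$y - points$y[i])^2
    v <- cells$temperature[d2 <= radius^2]
    v <- v[!is.na(v)]
    if (length(v) < min_cells) return(NA_real_)
    q <- stats::quantile(v, c(0.1, 0.9), type = 7, names = FALSE)
    q[2] - q[1]
  })
  dplyr::mutate(points, t_var = vals)
}

#' Microclimate buffering potential
#'
#' `t_bp = t_var / delta_t`: the sign follows the temperature change, and
#' `|t_bp| > 1` means the spatial variability within the buffer exceeds the
#' temporal change, so nearby microclimates can (temporarily) buffer the
#' trend. A change below 1e-6 deg C in magnitude maps to a signed infinity
#' sentinel and the top class: spatial variability trivially exceeds no
#' change.
#'
#' @param t_var Spatial variability, deg C (>= 0).
#' @param delta_t Temporal change, deg C.
#' @return Tibble with `t_bp` and `t_bp_class` (factor with levels
#'   `<=-10`, `(-10,-1]`, `(-1,1]`, `(1,10]`, `>10`).
#' @export
t_bp <- function(t_var, delta_t) {
  if (any(t_var < 0, na.rm = TRUE)) stop("t_var must be >= 0", call. = FALSE)
  tiny <- abs(delta_t) < 1e-6
  ratio <- ifelse(tiny, Inf, t_var / delta_t)
  cls <- cut(ratio, breaks = c(-Inf, -10, -1, 1, 10, Inf),
             labels = c("<=-10", "(-10,-1]", "(-1,1]", "(1,10]", ">10"),
             right = TRUE)
  cls[tiny & !is.na(delta_t)] <- ">10"
  tibble::tibble(t_bp = ratio, t_bp_class = cls)
}

#' Summaries of microclimate change by latitudinal band and distance class
#'
#' @param records Tibble with `band`, `distance_class`, `delta_t`, optional
#'   `season_change` (days) and `t_bp_class`.
#' @return List with `changes` (per-group mean, sd, median, quartiles) and
#'   `buffering` (per-group class percentages, summing to 100 within each
#'   group); empty groups are omitted.
#' @export
summarize_buffering <- function(records) {
  if (nrow(records) == 0) stop("no records to summarize", call. = FALSE)
  grp <- c("band", "distance_class")
  q <- function(x, p) stats::quantile(x, p, type = 7, names = FALSE, na.rm = TRUE)
  changes <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_delta_t = mean(.data$delta_t, na.rm = TRUE),
      sd_delta_t = stats::sd(.data$delta_t),
      median_delta_t = stats::median(.data$delta_t, na.rm = TRUE),
      q25_delta_t = q(.data$delta_t, 0.25),
      q75_delta_t = q(.data$delta_t, 0.75),
      mean_season_change = if ("season_change" %in% names(records)) {
        mean(.data$season_change, na.rm = TRUE)
      } else NA_real_,
      sd_season_change = if ("season_change" %in% names(records)) {
        stats::sd(.data$season_change)
      } else NA_real_,
      .groups = "drop"
    )
  buffering <- NULL
  if ("t_bp_class" %in% names(records)) {
    buffering <- records |>
      dplyr::filter(!is.na(.data$t_bp_class)) |>
      dplyr::count(dplyr::across(dplyr::all_of(c(grp, "t_bp_class")))) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  list(changes = changes, buffering = buffering)
}

#' Extrapolation audit of projection inputs
#'
#' Percentage of projection values falling strictly outside the training
#' range, per predictor.
#'
#' @param projection Tibble of projection covariates.
#' @param training_ranges Tibble with `term`, `min`, `max` (see
#'   [training_ranges()]).
#' @return Tibble with `term`, `n`, `pct_outside`.
#' @export
extrapolation_audit <- function(projection, training_ranges) {
  purrr::map_dfr(seq_len(nrow(training_ranges)), function(i) {
    tm <- training_ranges$term[i]
    if (!tm %in% names(projection)) return(NULL)
    x <- projection[[tm]]
    x <- x[!is.na(x)]
    tibble::tibble(
      term = tm,
      n = length(x),
      pct_outside = 100 * mean(x < training_ranges$min[i] | x > training_ranges$max[i])
    )
  })
}

#' Training ranges of the raw predictors
#'
#' @param df Raw monthly covariate table (training plus validation rows).
#' @param terms Predictor columns to range over.
#' @return Tibble with `term`, `min`, `max`.
#' @export
training_ranges <- function(df, terms = c("mT", "rad", "sfd", "dg")) {
  purrr::map_dfr(terms, function(tm) {
    tibble::tibble(term = tm, min = min(df[[tm]], na.rm = TRUE),
                   max = max(df[[tm]], na.rm = TRUE))
  })
}
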