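#' Daily temperature range of a logger trace
#'
#' A device buried under snow shows a strongly damped diurnal cycle, so the
#' daily max-min range separates snow-covered from snow-free days. Days with
#' fewer than `min_records` observations are marked invalid (range `NA`)
#' rather than erroring: sparse days would otherwise produce spuriously
#' small ranges.
#'
#' @param trace Tibble with `timestamp` (POSIXct, UTC) and `temperature`
#'   (deg C); extra columns pass through grouping by `station_id` if present.
#' @param min_records Minimum records per calendar day (default 4).
#' @return Tibble with `station_id` (if present), `date`, `n_records`,
#'   `range` (deg C, `NA` on invalid days).
#' @export
daily_range <- function(trace, min_records = 4) {
  keys <- intersect("station_id", names(trace))
  trace |>
    dplyr::mutate(date = as.Date(.data$timestamp)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "date")))) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      range = max(.data$temperature) - min(.data$temperature),
      .groups = "drop"
    ) |>
    dplyr::mutate(range = ifelse(.data$n_records >= min_records, .data$range, NA_real_))
}

#' Sensor-derived monthly snow-free-day frequency
#'
#' A day is snow-free when its diurnal range reaches `threshold` (snow is
#' inferred when the range is strictly below it). The monthly frequency is
#' `100 * snow-free days / valid days`; with `denominator = "calendar"` the
#' month's calendar days are used instead of observed valid days. Months
#' with zero valid days return `NA`.
#'
#' @param ranges Output of [daily_range()].
#' @param threshold Diurnal-range threshold in deg C (> 0); the calibrated
#'   default is 1.5.
#' @param denominator `"observed"` (valid days, default) or `"calendar"`.
#' @return Tibble with `station_id` (if present), `year`, `month`,
#'   `n_valid`, `sfd_sensor` (percent).
#' @export
sensor_sfd <- function(ranges, threshold = 1.5, denominator = c("observed", "calendar")) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  denominator <- match.arg(denominator)
  keys <- intersect("station_id", names(ranges))
  out <- ranges |>
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "year", "month")))) |>
    dplyr::summarise(
      n_valid = sum(!is.na(.data$range)),
      n_free = sum(.data$range >= threshold, na.rm = TRUE),
      .groups = "drop"
    )
  denom <- if (denominator == "observed") {
    out$n_valid
  } else {
    days_in_month(out$year, out$month)
  }
  out |>
    dplyr::mutate(sfd_sensor = ifelse(.data$n_valid == 0, NA_real_,
                                      100 * .data$n_free / denom)) |>
    dplyr::select(-"n_free")
}

#' Satellite-derived monthly snow-free-day frequency
#'
#' Converts daily fractional snow cover to snow occurrence with the
#' conservative 40% threshold (snow present iff cover >= 40%; snow-free
#' strictly below). Months supported by fewer than `min_images` valid days
#' are returned as missing.
#'
#' @param cover Tibble with `date`, `fractional_cover` (percent in
#'   `[0, 100]` or `NA` for cloud/polar-night gaps), optional `station_id`.
#' @param snow_threshold Fractional-cover threshold, percent (default 40).
#' @param min_images Minimum valid images per month (default 15).
#' @param denominator `"observed"` valid days (default) or `"calendar"`.
#' @return Tibble with `station_id` (if present), `year`, `month`,
#'   `n_images`, `sfd_satellite` (percent, `NA` under the image minimum).
#' @export
satellite_sfd <- function(cover, snow_threshold = 40, min_images = 15,
                          denominator = c("observed", "calendar")) {
  denominator <- match.arg(denominator)
  ok <- !is.na(cover$fractional_cover)
  if (any(cover$fractional_cover[ok] < 0 | cover$fractional_cover[ok] > 100)) {
    stop("fractional cover must lie in [0, 100] or be NA", call. = FALSE)
  }
  keys <- intersect("station_id", names(cover))
  out <- cover |>
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "year", "month")))) |>
    dplyr::summarise(
      n_images = sum(!is.na(.data$fractional_cover)),
      n_free = sum(.data$fractional_cover < snow_threshold, na.rm = TRUE),
      .groups = "drop"
    )
  denom <- if (denominator == "observed") {
    out$n_images
  } else {
    days_in_month(out$year, out$month)
  }
  out |>
    dplyr::mutate(sfd_satellite = ifelse(.data$n_images < min_images, NA_real_,
                                         100 * .data$n_free / denom)) |>
    dplyr::select(-"n_free")
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- as.Date(ifelse(month == 12, sprintf("%d-01-01", year + 1),
                        sprintf("%d-%02d-01", year, month + 1)))
  as.integer(nxt - first)
}

#' Calibrate the sensor snow threshold against satellite snow cover
#'
#' Sweeps the grid of diurnal-range thresholds (0.5--3 deg C) and
#' minimum-image filters (1--20), computes the hierarchically weighted
#' agreement (wR2, wMAE, wRMSE) between sensor and satellite monthly
#' snow-free-day frequencies on matched station-months, and selects the
#' combination maximizing wR2 (ties broken by the smaller wRMSE).
#'
#' @param ranges Output of [daily_range()] (all stations).
#' @param cover Daily fractional-cover tibble as in [satellite_sfd()].
#' @param stations Tibble mapping `station_id` to `glacier_id` and `region`
#'   (the weighting levels).
#' @param thresholds Candidate diurnal-range thresholds, deg C.
#' @param min_images Candidate minimum-image filters.
#' @return List with `grid` (one row per combination with wR2/wMAE/wRMSE and
#'   `n_months`) and `selected` (the chosen row), classed
#'   `fc_snow_calibration`.
#' @export
calibrate_snow <- function(ranges, cover, stations,
                           thresholds = c(0.5, 1, 1.5, 2, 2.5, 3),
                           min_images = c(1, 5, 10, 15, 20)) {
  sat_all <- satellite_sfd(cover, min_images = 1)
  combos <- tidyr::expand_grid(threshold = thresholds, min_images = min_images)
  grid <- purrr::pmap_dfr(combos, function(threshold, min_images) {
    sen <- sensor_sfd(ranges, threshold = threshold)
    sat <- dplyr::mutate(
      sat_all,
      sfd_satellite = ifelse(.data$n_images < min_images, NA_real_, .data$sfd_satellite)
    )
    matched <- dplyr::inner_join(
      sen, sat, by = intersect(names(sen), c("station_id", "year", "month"))
    ) |>
      dplyr::filter(!is.na(.data$sfd_sensor), !is.na(.data$sfd_satellite)) |>
      dplyr::left_join(stations, by = "station_id")
    if (nrow(matched) < 2) {
      return(tibble::tibble(
        threshold = threshold, min_images = min_images, n_months = nrow(matched),
        wr2 = NA_real_, wmae = NA_real_, wrmse = NA_real_
      ))
    }
    w <- build_weights(
      dplyr::mutate(matched, sfd = .data$sfd_satellite),
      region = "region", group = "glacier_id"
    )
    stats <- weighted_stats(matched$sfd_sensor, matched$sfd_satellite, w$weight)
    tibble::tibble(
      threshold = threshold, min_images = min_images, n_months = nrow(matched),
      wr2 = stats$wr2, wmae = stats$wmae, wrmse = stats$wrmse
    )
  })
  if (all(is.na(grid$wr2))) {
    stop("no overlapping sensor/satellite months: cannot calibrate", call. = FALSE)
  }
  ranked <- grid |>
    dplyr::filter(!is.na(.data$wr2)) |>
    dplyr::arrange(dplyr::desc(.data$wr2), .data$wrmse)
  structure(list(grid = grid, selected = ranked[1, ]), class = "fc_snow_calibration")
}

#' @export
print.fc_snow_calibration <- function(x, ...) {
  s <- x$selected
  cat(sprintf(
    "snow calibration: threshold %.1f degC, >= %d images (wR2 %.3f, wMAE %.2f%%, wRMSE %.2f%%)\n",
    s$threshold, s$min_images, s$wr2, s$wmae, s$wrmse
  ))
  invisible(x)
}

#' Snow-free season duration
#'
#' Counts snow-free days (fractional cover strictly below the threshold)
#' per calendar year and averages across the years of the period. With
#' cloud gaps, the observed snow-free share is rescaled to the year length,
#' so a gap-free year reduces to a plain day count.
#'
#' @inheritParams satellite_sfd
#' @return Tibble with `station_id` (if present) and `season_days` (mean
#'   snow-free days per year; `NA` if a year has no valid images).
#' @export
season_duration <- function(cover, snow_threshold = 40) {
  keys <- intersect("station_id", names(cover))
  per_year <- cover |>
    dplyr::mutate(year = as.integer(format(.data$date, "%Y"))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "year")))) |>
    dplyr::summarise(
      n_valid = sum(!is.na(.data$fractional_cover)),
      n_free = sum(.data$fractional_cover < snow_threshold, na.rm = TRUE),
      n_days = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      year_length = days_in_year(.data$year),
      season = ifelse(.data$n_valid == 0, NA_real_,
                      .data$year_length * .data$n_free / .data$n_valid)
    )
  per_year |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(season_days = mean(.data$season), .groups = "drop")
}

days_in_year <- function(year) {
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}
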