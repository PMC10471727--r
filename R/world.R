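#' Configuration for the synthetic proglacial world
#'
#' Defines the study conditions the generator emulates: a set of glacier
#' forelands spread across latitudes, stations with burial depths 5/10/15 cm,
#' monthly macroclimate with seasonality and a warming trend, insolation,
#' per-station snow calendars, and soil temperatures generated from the
#' full mixed model (standardized design, per-glacier random intercepts,
#' residual noise), with snowpack decoupling below 20% snow-free days.
#'
#' `true_coefficients` are on the standardized scale (the scale on which the
#' model is fitted); [default_true_coefficients()] carries the package
#' defaults, with the field-expected signs: positive macroclimate,
#' radiation, snow-free-day and distance effects, negative depth and tree
#' cover, a small negative permafrost effect.
#'
#' @param n_glaciers Number of glacier forelands (>= 1).
#' @param stations_per_glacier Stations per foreland (>= 1).
#' @param n_months Months of record per station (>= 1).
#' @param dem_size DEM side length in cells (>= 16) for the demo foreland.
#' @param cell_size DEM cell size, m.
#' @param relief Vertical relief of the demo DEM, m (0 gives a flat world).
#' @param true_coefficients Named vector of fixed coefficients on the
#'   standardized scale; names must match [model_term_names()].
#' @param glacier_intercept_sd SD of per-glacier random intercepts, deg C.
#' @param residual_sd SD of monthly residuals, deg C. Hourly AR(1) noise in
#'   logger traces scales with it, so `residual_sd = 0` gives an exactly
#'   noise-free world.
#' @param diurnal_amplitude_snowfree,diurnal_amplitude_snow Sinusoid
#'   amplitude of the hourly diurnal cycle (deg C; daily range is twice the
#'   amplitude). The snow amplitude must be strictly smaller: the amplitude
#'   gap is what makes snow detectable from the diurnal range.
#' @param cloud_missing_prob Probability that a satellite snow-cover day is
#'   missing (cloud / polar night), in `[0, 1]`.
#' @param trend Macroclimate warming trend, deg C per decade.
#' @param start_year First calendar year of the record.
#' @param seed Integer master seed; every draw flows from named substreams
#'   of it, so identical configs reproduce the world bit-for-bit.
#' @return A validated `fc_world_config` list.
#' @export
world_config <- function(n_glaciers = 20, stations_per_glacier = 6,
                         n_months = 24, dem_size = 48, cell_size = 30,
                         relief = 400,
                         true_coefficients = default_true_coefficients(),
                         glacier_intercept_sd = 1.5, residual_sd = 1.5,
                         diurnal_amplitude_snowfree = 5,
                         diurnal_amplitude_snow = 0.2,
                         cloud_missing_prob = 0.2, trend = 0.5,
                         start_year = 2018, seed = 1) {
  cfg <- list(
    n_glaciers = n_glaciers, stations_per_glacier = stations_per_glacier,
    n_months = n_months, dem_size = dem_size, cell_size = cell_size,
    relief = relief, true_coefficients = true_coefficients,
    glacier_intercept_sd = glacier_intercept_sd, residual_sd = residual_sd,
    diurnal_amplitude_snowfree = diurnal_amplitude_snowfree,
    diurnal_amplitude_snow = diurnal_amplitude_snow,
    cloud_missing_prob = cloud_missing_prob, trend = trend,
    start_year = start_year, seed = seed
  )
  counts <- c("n_glaciers", "stations_per_glacier", "n_months")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) {
      stop("invalid configuration: ", f, " must be a count >= 1", call. = FALSE)
    }
  }
  if (dem_size < 16) stop("invalid configuration: dem_size must be >= 16", call. = FALSE)
  for (f in c("glacier_intercept_sd", "residual_sd", "relief",
              "diurnal_amplitude_snowfree", "diurnal_amplitude_snow")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      stop("invalid configuration: ", f, " must be >= 0", call. = FALSE)
    }
  }
  if (cloud_missing_prob < 0 || cloud_missing_prob > 1) {
    stop("invalid configuration: cloud_missing_prob must lie in [0, 1]", call. = FALSE)
  }
  if (diurnal_amplitude_snow >= diurnal_amplitude_snowfree) {
    stop("invalid configuration: diurnal_amplitude_snow must be < diurnal_amplitude_snowfree",
         call. = FALSE)
  }
  miss <- setdiff(model_term_names(), names(true_coefficients))
  if (length(miss) > 0) {
    stop("invalid configuration: true_coefficients missing term(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "fc_world_config")
}

#' Default generating coefficients (standardized scale)
#'
#' @return Named numeric vector over [model_term_names()].
#' @export
default_true_coefficients <- function() {
  c(
    "(Intercept)" = 5, mT = 3, rad = 1, sfd = 1.5, dg = 0.5,
    tc = -1, pf = -0.8, d = -0.4,
    "mT:sfd" = 0.8, "rad:sfd" = 0.4, "sfd:dg" = -0.3, "sfd:d" = -0.35,
    "rad:tc" = -0.25
  )
}

# named substreams: every artifact draws from its own deterministic stream
substream_seed <- function(seed, name) {
  ids <- c(
    terrain = 11, stations = 23, climate = 37, snow = 53, soil = 71,
    traces = 89, satellite = 97, sampling = 113
  )
  (abs(as.integer(seed)) %% 1000000L) * 1009L + ids[[name]]
}

#' Generate the demo foreland terrain and glacier outlines
#'
#' Builds a smooth synthetic DEM (ridge plus low-frequency noise scaled by
#' `relief`; `relief = 0` gives a perfectly flat world) and two glacier
#' outlines: epoch 2 is a concentric contraction of epoch 1, so retreat and
#' outline nesting hold by construction.
#'
#' @param config An [world_config()].
#' @return List with `terrain` ([slope_aspect()] output) and `outlines`
#'   (list of `epoch1`, `epoch2` vertex matrices in grid meters).
#' @export
generate_terrain <- function(config) {
  stopifnot(inherits(config, "fc_world_config"))
  set.seed(substream_seed(config$seed, "terrain"))
  n <- config$dem_size
  cs <- config$cell_size
  xy <- grid_coordinates(fc_grid(matrix(0, n, n), cs))
  ext <- n * cs
  # north-facing valley head: elevation rises northwards and towards edges
  base <- config$relief * (0.6 * (xy$y / ext) +
                             0.4 * ((xy$x - ext / 2) / ext)^2 * 4)
  if (config$relief > 0) {
    ph <- stats::runif(4, 0, 2 * pi)
    noise <- config$relief * 0.08 * (
      sin(2 * pi * xy$x / ext + ph[1]) * cos(2 * pi * xy$y / ext + ph[2]) +
        0.5 * sin(4 * pi * xy$x / ext + ph[3]) * cos(4 * pi * xy$y / ext + ph[4])
    )
  } else {
    noise <- 0
  }
  elev <- fc_grid(matrix(base + noise, n, n), cs)
  terrain <- slope_aspect(elev)

  cx <- ext / 2
  cy <- ext * 0.8
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  r1 <- ext * 0.18
  r2 <- r1 * 0.65
  outlines <- list(
    epoch1 = cbind(x = cx + r1 * cos(th), y = cy + r1 * sin(th)),
    epoch2 = cbind(x = cx + r2 * cos(th), y = cy + r2 * sin(th))
  )
  list(terrain = terrain, outlines = outlines)
}

#' Simulate a synthetic proglacial world
#'
#' Generates glaciers with latitudes spanning polar to equatorial bands
#' (guaranteeing at least two weighting regions), stations with geography
#' and covariates, monthly macroclimate/radiation series, daily snow
#' calendars, and monthly soil temperatures drawn from the full mixed model
#' on the standardized design. Months with snow-free-day frequency at or
#' below 20% are snow-decoupled: their soil temperature sits near 0 deg C
#' regardless of the predictors, as under an insulating snowpack.
#'
#' All ground truth needed by downstream tests is stored: realized
#' standardized coefficients, glacier intercepts, the standardization table,
#' the snow calendar and the deterministic monthly means.
#'
#' @param config An [world_config()].
#' @return An `fc_world` list: `config`, `terrain`, `outlines`, `stations`,
#'   `months`, `snow_calendar`, `truth`.
#' @export
simulate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "fc_world_config"))
  geo <- generate_terrain(config)

  set.seed(substream_seed(config$seed, "stations"))
  ng <- config$n_glaciers
  sg <- config$stations_per_glacier
  lat_g <- seq(-55, 70, length.out = max(ng, 2))[seq_len(ng)]
  if (ng == 1) lat_g <- 46
  lon_g <- stats::runif(ng, -180, 180)
  elev_g <- 700 + 2600 * (1 - abs(lat_g) / 90) + stats::rnorm(ng, 0, 150)
  region_g <- ifelse(abs(lat_g) <= 23.44, "Equatorial",
                     ifelse(abs(lat_g) < 60, "Mid-latitudes", "Polar"))
  glaciers <- tibble::tibble(
    glacier_id = sprintf("g%02d", seq_len(ng)),
    lat = lat_g, lon = lon_g, base_elevation = elev_g, region = region_g
  )

  stations <- glaciers |>
    dplyr::reframe(
      station_id = sprintf("%s_s%02d", .data$glacier_id, seq_len(sg)),
      lat = .data$lat + stats::runif(sg, -0.01, 0.01),
      lon = .data$lon + stats::runif(sg, -0.01, 0.01),
      elevation = .data$base_elevation + stats::runif(sg, -200, 300),
      depth_cm = rep(c(5, 10, 15), length.out = sg),
      dg = stats::runif(sg, 20, 3000),
      tc = stats::rbinom(sg, 1, 0.3),
      pf = stats::rbinom(sg, 1, stats::plogis((.data$base_elevation - 2800) / 300)),
      .by = "glacier_id"
    ) |>
    dplyr::left_join(dplyr::select(glaciers, "glacier_id", "region"), by = "glacier_id")

  set.seed(substream_seed(config$seed, "climate"))
  mseq <- tibble::tibble(month_index = seq_len(config$n_months)) |>
    dplyr::mutate(
      year = config$start_year + (.data$month_index - 1) %/% 12,
      month = (.data$month_index - 1) %% 12 + 1
    )
  months <- tidyr::expand_grid(
    station_id = stations$station_id, month_index = mseq$month_index
  ) |>
    dplyr::left_join(mseq, by = "month_index") |>
    dplyr::left_join(stations, by = "station_id")

  doy_mid <- as.integer(strftime(
    as.Date(sprintf("%d-%02d-15", months$year, months$month)), "%j"
  ))
  decl <- 23.44 * sin(2 * pi * (doy_mid - 81) / 365)
  seas_amp <- 2 + 16 * abs(months$lat) / 90
  phase <- cos(2 * pi * (months$month - 7) / 12) * sign(months$lat + 1e-9)
  years_elapsed <- (months$month_index - 1) / 12
  months$mT <- 27 - 0.38 * abs(months$lat) - 0.0065 * months$elevation +
    seas_amp * phase + config$trend * years_elapsed / 10 +
    stats::rnorm(nrow(months), 0, 0.8)
  months$rad <- pmax(
    0.5,
    30 * pmax(0.03, cos((months$lat - decl) * pi / 180)) * 0.65 +
      stats::rnorm(nrow(months), 0, 1.5)
  )

  # daily snow calendar: snow when the downscaled monthly macroclimate plus
  # per-day jitter is below freezing; this builds the sfd-elevation and
  # sfd-season covariance the model exploits
  set.seed(substream_seed(config$seed, "snow"))
  ndays <- days_in_month(months$year, months$month)
  calendar <- months |>
    dplyr::select("station_id", "year", "month", "mT") |>
    dplyr::mutate(n_days = ndays) |>
    tidyr::uncount(.data$n_days, .id = "day") |>
    dplyr::mutate(
      date = as.Date(sprintf("%d-%02d-%02d", .data$year, .data$month, .data$day)),
      snow = .data$mT + stats::rnorm(dplyr::n(), 0, 2) < 0
    ) |>
    dplyr::select("station_id", "date", "snow")

  sfd_tbl <- calendar |>
    dplyr::mutate(
      year = as.integer(format(.data$date, "%Y")),
      month = as.integer(format(.data$date, "%m"))
    ) |>
    dplyr::group_by(.data$station_id, .data$year, .data$month) |>
    dplyr::summarise(sfd = 100 * mean(!.data$snow), .groups = "drop")
  months <- dplyr::left_join(months, sfd_tbl, by = c("station_id", "year", "month"))

  # soil temperature from the standardized design, exactly as the model is fit
  set.seed(substream_seed(config$seed, "soil"))
  u <- stats::rnorm(ng, 0, config$glacier_intercept_sd)
  intercepts <- tibble::tibble(glacier_id = glaciers$glacier_id, intercept = u)

  retained <- months$sfd > 20
  std <- compute_standardization(months[retained, ])
  xs <- standardize_design(months, std)
  mm <- model_matrix_fixed(xs)
  beta <- config$true_coefficients[colnames(mm)]
  mu_fixed <- as.vector(mm %*% beta)
  uvec <- intercepts$intercept[match(months$glacier_id, intercepts$glacier_id)]

  months$mu_fixed <- ifelse(retained, mu_fixed, 0)
  months$mu <- ifelse(retained, mu_fixed + uvec, 0)
  eps_sd <- ifelse(retained, config$residual_sd, 0.2 * config$residual_sd)
  months$soilT <- months$mu + stats::rnorm(nrow(months), 0, eps_sd)
  months$gl <- months$glacier_id

  structure(
    list(
      config = config,
      terrain = geo$terrain,
      outlines = geo$outlines,
      stations = stations,
      months = dplyr::select(
        months, "station_id", "glacier_id", "gl", "region", "month_index",
        "year", "month", "mT", "rad", "sfd", "dg", "tc", "pf",
        depth_cm = "depth_cm", "elevation", "lat", "lon",
        "mu_fixed", "mu", "soilT"
      ),
      snow_calendar = calendar,
      truth = list(
        coefficients = beta,
        glacier_intercepts = intercepts,
        standardization = std,
        retained = retained
      )
    ),
    class = "fc_world"
  )
}

#' @export
print.fc_world <- function(x, ...) {
  cat(sprintf(
    "<fc_world> %d glaciers x %d stations x %d months (seed %d)\n",
    x$config$n_glaciers, x$config$stations_per_glacier,
    x$config$n_months, x$config$seed
  ))
  cat(sprintf("  %d station-months, %d with sfd > 20%%\n",
              nrow(x$months), sum(x$months$sfd > 20)))
  invisible(x)
}

#' Generate hourly logger traces from a synthetic world
#'
#' Hourly temperature = the station-month's (noisy) monthly mean, plus a
#' diurnal sinusoid whose amplitude is `diurnal_amplitude_snow` on
#' snow-covered days and `diurnal_amplitude_snowfree` otherwise, plus AR(1)
#' noise with lag-1 correlation 0.6 whose innovation scale is proportional
#' to `residual_sd` (so a zero-residual world yields exactly deterministic
#' traces). Generated only for the requested stations: hourly series are
#' bulky and most stages need only a handful of stations.
#'
#' @param world An `fc_world` from [simulate_world()].
#' @param station_ids Stations to generate (default: all).
#' @return Tibble with `station_id`, `timestamp` (POSIXct UTC, hourly),
#'   `temperature` plus station metadata columns.
#' @export
generate_logger_traces <- function(world, station_ids = NULL) {
  stopifnot(inherits(world, "fc_world"))
  cfg <- world$config
  if (is.null(station_ids)) station_ids <- world$stations$station_id
  set.seed(substream_seed(cfg$seed, "traces"))
  rho <- 0.6
  innov_sd <- 0.15 * cfg$residual_sd

  cal <- world$snow_calendar |>
    dplyr::filter(.data$station_id %in% station_ids)
  mon <- world$months |>
    dplyr::filter(.data$station_id %in% station_ids) |>
    dplyr::select("station_id", "year", "month", "soilT")

  hours <- cal |>
    dplyr::left_join(
      dplyr::mutate(mon, date_key = paste(.data$year, .data$month)),
      by = c("station_id"),
      relationship = "many-to-many"
    )
  # the join above fans out; keep the matching month only
  hours <- hours |>
    dplyr::filter(
      as.integer(format(.data$date, "%Y")) == .data$year,
      as.integer(format(.data$date, "%m")) == .data$month
    ) |>
    dplyr::select("station_id", "date", "snow", "soilT")

  out <- hours[rep(seq_len(nrow(hours)), each = 24), ]
  out$hour <- rep(0:23, times = nrow(hours))
  amp <- ifelse(out$snow, cfg$diurnal_amplitude_snow, cfg$diurnal_amplitude_snowfree)
  diurnal <- amp * sin(2 * pi * (out$hour - 9) / 24)

  noise <- numeric(nrow(out))
  if (innov_sd > 0) {
    for (sid in unique(out$station_id)) {
      sel <- which(out$station_id == sid)
      e <- stats::rnorm(length(sel), 0, innov_sd)
      noise[sel] <- as.vector(stats::filter(e, rho, method = "recursive"))
    }
  }
  meta <- dplyr::select(world$stations, "station_id", "glacier_id", "region",
                        "lat", "lon", "elevation", "depth_cm")
  tibble::tibble(
    station_id = out$station_id,
    timestamp = as.POSIXct(out$date, tz = "UTC") + out$hour * 3600,
    temperature = out$soilT + diurnal + noise
  ) |>
    dplyr::left_join(meta, by = "station_id") |>
    dplyr::arrange(.data$station_id, .data$timestamp)
}

#' Generate daily satellite fractional snow cover for a world
#'
#' Snow-covered days draw fractional cover uniformly in `[40, 100]`,
#' snow-free days in `[0, 40)`; each day is independently missing with
#' probability `cloud_missing_prob` (clouds, polar night).
#'
#' @param world An `fc_world`.
#' @param station_ids Stations to generate (default: all).
#' @return Tibble with `station_id`, `date`, `fractional_cover` (percent,
#'   `NA` when missing).
#' @export
generate_satellite_snow <- function(world, station_ids = NULL) {
  stopifnot(inherits(world, "fc_world"))
  cfg <- world$config
  if (is.null(station_ids)) station_ids <- world$stations$station_id
  set.seed(substream_seed(cfg$seed, "satellite"))
  cal <- world$snow_calendar |>
    dplyr::filter(.data$station_id %in% station_ids)
  n <- nrow(cal)
  cover <- ifelse(cal$snow, stats::runif(n, 40, 100), stats::runif(n, 0, 39.99))
  miss <- stats::runif(n) < cfg$cloud_missing_prob
  tibble::tibble(
    station_id = cal$station_id,
    date = cal$date,
    fractional_cover = ifelse(miss, NA_real_, cover)
  )
}
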