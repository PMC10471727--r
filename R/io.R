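#' Read and write logger CSV files
#'
#' The logger schema is one row per record: `station_id`, `glacier_id`,
#' `region`, `latitude`, `longitude` (EPSG:4326), `elevation` (m),
#' `depth_cm` (5/10/15), `nominal_frequency` (records/day), `timestamp`
#' (ISO-8601 UTC) and `temperature` (deg C). On read, duplicate timestamps
#' within a station are collapsed by their mean (with a warning) and rows
#' outside the [-60, 60] deg C sanity window are rejected (with a count).
#'
#' @param path CSV file path.
#' @return Tibble of logger records, timestamps as POSIXct UTC, sorted by
#'   station and time.
#' @export
read_loggers <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) stop("empty logger file: ", path, call. = FALSE)
  need <- c("station_id", "glacier_id", "region", "latitude", "longitude",
            "elevation", "depth_cm", "nominal_frequency", "timestamp",
            "temperature")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("logger file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(df$timestamp, "POSIXct")) {
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  }
  attr(df$timestamp, "tzone") <- "UTC"
  bad <- is.na(df$temperature) | df$temperature < -60 | df$temperature > 60
  if (any(bad)) {
    warning(sum(bad), " record(s) outside the [-60, 60] degC sanity window rejected")
    df <- df[!bad, ]
  }
  dup <- duplicated(df[, c("station_id", "timestamp")])
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) collapsed by mean")
    df <- df |>
      dplyr::group_by(dplyr::across(-"temperature")) |>
      dplyr::summarise(temperature = mean(.data$temperature), .groups = "drop")
  }
  dplyr::arrange(df, .data$station_id, .data$timestamp)
}

#' @param df Logger tibble in the schema above.
#' @rdname read_loggers
#' @export
write_loggers <- function(df, path) {
  out <- dplyr::mutate(
    df, timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write glacier outlines as GeoJSON
#'
#' @param outlines Named list of polygons (two-column x/y vertex matrices).
#' @param path Output path.
#' @param crs CRS label recorded in the file properties.
#' @return `path`, invisibly.
#' @export
write_outlines_geojson <- function(outlines, path, crs = "local-metric") {
  features <- purrr::imap(outlines, function(p, nm) {
    p <- as.matrix(as.data.frame(p)[, 1:2])
    ring <- rbind(p, p[1, , drop = FALSE]) # close the ring
    list(
      type = "Feature",
      properties = list(name = nm, crs = crs),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
          c(ring[i, 1], ring[i, 2])
        }))
      )
    )
  })
  obj <- list(type = "FeatureCollection",
              features = unname(features))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read glacier outlines from GeoJSON
#'
#' @param path GeoJSON path written by [write_outlines_geojson()].
#' @return Named list of two-column vertex matrices.
#' @export
read_outlines_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  out <- lapply(obj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    colnames(ring) <- c("x", "y")
    ring[-nrow(ring), , drop = FALSE] # drop closing vertex
  })
  names(out) <- vapply(obj$features, function(f) f$properties$name, character(1))
  out
}

#' Default pipeline configuration
#'
#' One declarative list with a section per stage; defaults mirror the
#' pipeline constants: lapse rate -0.0065 deg C/m, satellite snow threshold
#' 40%, sensor diurnal-range threshold 1.5 deg C, minimum 15 images,
#' snow-decoupling cutoff sfd > 20%, permafrost probability 0.9, and 1000
#' permutations/bootstraps (reduced in the demo for speed).
#'
#' @param seed Master seed (mandatory for a run).
#' @return Nested configuration list.
#' @export
demo_config <- function(seed = 1) {
  list(
    seed = seed,
    world = list(
      n_glaciers = 8, stations_per_glacier = 5, n_months = 24,
      dem_size = 32, cell_size = 30, residual_sd = 1.0
    ),
    downscale = list(lapse_rate = -0.0065),
    snow = list(snow_threshold = 40, sensor_threshold = 1.5, min_images = 15),
    model = list(sfd_cutoff = 20, n_perm = 25, n_bootstrap = 0),
    projection = list(year_gap = 15, depth_cm = 5)
  )
}

#' Run the full demo pipeline
#'
#' Chains simulate -> snow -> fit -> leave-one-out -> validate -> project ->
#' buffering on a synthetic world and writes every tabular artifact as CSV
#' plus a JSON manifest (config, seed) into `out_dir`. Re-running with the
#' same config reproduces the outputs byte for byte.
#'
#' @param config Configuration list as from [demo_config()], or a path to a
#'   YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = demo_config(), out_dir = tempfile("fcrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must declare a seed", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  wc <- do.call(world_config, c(config$world, list(seed = config$seed)))
  world <- stage("simulate", simulate_world(wc))
  message(sprintf("simulate: %d stations, %d station-months",
                  nrow(world$stations), nrow(world$months)))

  cover <- stage("snow", generate_satellite_snow(world))
  sat <- satellite_sfd(cover, snow_threshold = config$snow$snow_threshold,
                       min_images = config$snow$min_images)
  message(sprintf("snow: %d station-months with satellite sfd",
                  sum(!is.na(sat$sfd_satellite))))

  design <- stage("fit", build_design(world$months,
                                      sfd_cutoff = config$model$sfd_cutoff))
  fit <- stage("fit", fit_soil_lmm(design))
  message(sprintf("fit: %d rows -> R2m %.3f R2c %.3f", nrow(design), fit$r2m, fit$r2c))

  loo <- stage("loo", loo_by_glacier(design))
  valid <- stage("validate", {
    preds <- predict_mean_coefficients(loo, design)
    preds$region <- design$region
    preds$glacier_id <- design$glacier_id
    preds$sfd_raw <- world$months$sfd[world$months$sfd > config$model$sfd_cutoff]
    validate_predictions(
      dplyr::mutate(preds, sfd = .data$sfd_raw),
      observed = "soilT", predicted = ".pred"
    )
  })
  message(sprintf("validate: wR2 %.3f wMAE %.3f wRMSE %.3f",
                  valid$wr2, valid$wmae, valid$wrmse))

  proj <- stage("project", {
    base <- world$months
    delta <- wc$trend * (config$projection$year_gap / 10)
    early <- dplyr::mutate(base, period = "early")
    late <- dplyr::mutate(base, mT = .data$mT + delta, period = "late")
    both <- dplyr::bind_rows(early, late)
    both$.pred <- project_soil_temperature(
      loo$mean_coefficients, loo$standardization, both,
      depth_cm = config$projection$depth_cm,
      sfd_cutoff = config$model$sfd_cutoff
    )$.pred
    both
  })

  buffering <- stage("buffering", {
    temps <- proj |>
      dplyr::transmute(point_id = .data$station_id, period = .data$period,
                       month = .data$month, temperature = .data$.pred)
    dt <- delta_t(temps, season = "annual")
    meta <- dplyr::distinct(world$stations, point_id = .data$station_id,
                            lat = .data$lat, dg = .data$dg)
    dt |>
      dplyr::left_join(meta, by = "point_id") |>
      dplyr::mutate(band = latitude_band(.data$lat))
  })

  readr::write_csv(world$months, file.path(out_dir, "monthly.csv"), progress = FALSE)
  readr::write_csv(sat, file.path(out_dir, "satellite_sfd.csv"), progress = FALSE)
  readr::write_csv(tidy(fit), file.path(out_dir, "fit_coefficients.csv"), progress = FALSE)
  readr::write_csv(loo$coefficients, file.path(out_dir, "loo_coefficients.csv"),
                   progress = FALSE)
  readr::write_csv(valid, file.path(out_dir, "validation.csv"), progress = FALSE)
  readr::write_csv(buffering, file.path(out_dir, "buffering.csv"), progress = FALSE)
  write_ascii_grid(world$terrain$elevation, file.path(out_dir, "dem.asc"))
  write_outlines_geojson(world$outlines, file.path(out_dir, "outlines.geojson"))
  jsonlite::write_json(
    list(seed = config$seed, config = config,
         r_version = as.character(getRversion())),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(world = world, satellite = sat, fit = fit, loo = loo,
                 validation = valid, buffering = buffering, out_dir = out_dir))
}
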